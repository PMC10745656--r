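#' Elman RNN configuration
#'
#' @param hidden_size hidden units. @param epochs maximum training epochs.
#' @param lr learning rate (SGD). @param bptt_len truncation length for
#'   backpropagation through time (chunks of this many steps; the hidden
#'   state is carried across chunks, gradients are not).
#' @param seed fixes weight initialization and sequence order.
#' @param init_scale sd of the Gaussian weight initialization.
#' @param clip global gradient-norm clip.
#' @param patience epochs without relative loss improvement before stopping.
#' @export
rnn_config <- function(hidden_size = 64, epochs = 200, lr = 0.01,
                       bptt_len = 50, seed = 1, init_scale = 0.1,
                       clip = 5, patience = 10) {
  assert_that(hidden_size > 0 && epochs > 0 && lr >= 0 && bptt_len > 0 &&
                init_scale > 0, "rnn_config values must be positive (lr >= 0)")
  structure(list(hidden_size = hidden_size, epochs = epochs, lr = lr,
                 bptt_len = bptt_len, seed = seed, init_scale = init_scale,
                 clip = clip, patience = patience),
            class = "rnn_config")
}

rnn_init <- function(d, L, cfg) {
  with_seed(derive_seed(cfg$seed, "rnn-init"), {
    h <- cfg$hidden_size
    list(Wxh = matrix(stats::rnorm(h * d, 0, cfg$init_scale), h, d),
         Whh = matrix(stats::rnorm(h * h, 0, cfg$init_scale), h, h),
         bh = numeric(h),
         Why = matrix(stats::rnorm(L * h, 0, cfg$init_scale), L, h),
         by = numeric(L))
  })
}

# Forward pass: returns hidden states, probabilities and total cross-entropy
rnn_forward <- function(params, X, y_idx = NULL, h0 = NULL) {
  Tn <- nrow(X)
  H <- length(params$bh); L <- length(params$by)
  hs <- matrix(0, Tn + 1, H)
  if (!is.null(h0)) hs[1, ] <- h0
  probs <- matrix(0, Tn, L)
  loss <- 0
  for (t in seq_len(Tn)) {
    hs[t + 1, ] <- tanh(params$Wxh %*% X[t, ] + params$Whh %*% hs[t, ] +
                          params$bh)
    z <- as.numeric(params$Why %*% hs[t + 1, ] + params$by)
    z <- z - max(z)
    p <- exp(z) / sum(exp(z))
    probs[t, ] <- p
    if (!is.null(y_idx)) loss <- loss - log(max(p[y_idx[t]], 1e-300))
  }
  list(hs = hs, probs = probs, loss = loss)
}

# Full BPTT gradients over one chunk
rnn_backward <- function(params, X, y_idx, fwd) {
  Tn <- nrow(X)
  g <- lapply(params, function(p) p * 0)
  dh_next <- numeric(length(params$bh))
  for (t in Tn:1) {
    dz <- fwd$probs[t, ]
    dz[y_idx[t]] <- dz[y_idx[t]] - 1
    g$Why <- g$Why + outer(dz, fwd$hs[t + 1, ])
    g$by <- g$by + dz
    dh <- as.numeric(crossprod(params$Why, dz)) + dh_next
    dr <- dh * (1 - fwd$hs[t + 1, ]^2)
    g$Wxh <- g$Wxh + outer(dr, X[t, ])
    g$Whh <- g$Whh + outer(dr, fwd$hs[t, ])
    g$bh <- g$bh + dr
    dh_next <- as.numeric(crossprod(params$Whh, dr))
  }
  g
}

#' Loss and analytic BPTT gradients for one sequence (no update)
#'
#' Exposed so gradients can be validated against finite differences.
#'
#' @param params RNN parameter list. @param X T x d inputs.
#' @param y_idx integer class indices per step.
#' @export
rnn_loss_grad <- function(params, X, y_idx) {
  fwd <- rnn_forward(params, X, y_idx)
  list(loss = fwd$loss, grads = rnn_backward(params, X, y_idx, fwd))
}

#' Train an Elman RNN on per-segment code sequences
#'
#' h_t = tanh(Wxh x_t + Whh h_(t-1) + bh), y_t = softmax(Why h_t + by),
#' cross-entropy loss, SGD with global gradient clipping and truncated BPTT.
#' Training stops early when the mean epoch loss plateaus.
#'
#' @param sequences list of T_i x d matrices (one per recording).
#' @param labels list of per-step label character vectors.
#' @param cfg an [rnn_config()].
#' @param classes optional fixed class vocabulary (defaults to the sorted
#'   labels observed).
#' @return an `rnn_model` with `params`, `classes`, `loss_trace`.
#' @export
rnn_train <- function(sequences, labels, cfg = rnn_config(), classes = NULL) {
  assert_that(length(sequences) == length(labels), "sequences/labels mismatch")
  dims <- unique(vapply(sequences, ncol, integer(1)))
  assert_that(length(dims) == 1, "all code vectors must have one length")
  if (is.null(classes)) classes <- sort(unique(unlist(labels)))
  assert_that(length(classes) >= 2, "need at least 2 classes")
  d <- dims; L <- length(classes)
  params <- rnn_init(d, L, cfg)
  y_all <- lapply(labels, function(l) {
    idx <- match(l, classes)
    assert_that(!anyNA(idx), "label outside the class vocabulary")
    idx
  })
  loss_trace <- numeric(0)
  best <- Inf; stall <- 0
  order_seed <- derive_seed(cfg$seed, "rnn-order")
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(order_seed + ep, sample(length(sequences)))
    ep_loss <- 0; ep_steps <- 0
    for (i in ord) {
      X <- sequences[[i]]; y <- y_all[[i]]
      h0 <- numeric(cfg$hidden_size)
      for (s in seq(1, nrow(X), by = cfg$bptt_len)) {
        e <- min(s + cfg$bptt_len - 1, nrow(X))
        Xc <- X[s:e, , drop = FALSE]; yc <- y[s:e]
        fwd <- rnn_forward(params, Xc, yc, h0)
        g <- rnn_backward(params, Xc, yc, fwd)
        gn <- sqrt(sum(vapply(g, function(m) sum(m^2), numeric(1))))
        sc <- if (gn > cfg$clip) cfg$clip / gn else 1
        if (!is.finite(fwd$loss)) stopf("NaN loss at epoch %d, sequence %d", ep, i)
        for (nm in names(params)) {
          params[[nm]] <- params[[nm]] - cfg$lr * sc * g[[nm]]
        }
        ep_loss <- ep_loss + fwd$loss; ep_steps <- ep_steps + (e - s + 1)
        h0 <- fwd$hs[nrow(fwd$hs), ]
      }
    }
    mean_loss <- ep_loss / ep_steps
    loss_trace <- c(loss_trace, mean_loss)
    if (!is.finite(best) || mean_loss < best - 1e-5 * abs(best)) {
      best <- mean_loss; stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= cfg$patience) break
    }
  }
  structure(list(params = params, classes = classes, d = d,
                 loss_trace = loss_trace, cfg = cfg), class = "rnn_model")
}

#' Predict per-step labels and class probabilities
#'
#' @param model an `rnn_model`. @param X T x d code sequence.
#' @return list with `labels` (length T) and `probs` (T x L, rows sum to 1).
#' @export
rnn_predict <- function(model, X) {
  X <- as.matrix(X)
  assert_that(ncol(X) == model$d, "input dim %d != model dim %d",
              ncol(X), model$d)
  fwd <- rnn_forward(model$params, X)
  list(labels = model$classes[apply(fwd$probs, 1, which.max)],
       probs = fwd$probs)
}

#' Classification metrics from predicted and true labels
#'
#' Builds the confusion matrix, derives one-vs-rest TP/TN/FP/FN per class and
#' reports accuracy (fraction of correctly decoded samples), with macro
#' averaged per-class accuracy, recall, precision and F1 (F1 = 0 when
#' precision + recall = 0).
#'
#' @param pred,truth equal-length label vectors.
#' @param classes optional fixed vocabulary.
#' @return an `eval_report`: `confusion`, `accuracy` (micro),
#'   `macro_accuracy`, `recall`, `precision`, `f1`, `per_class`.
#' @export
evaluate_predictions <- function(pred, truth, classes = NULL) {
  assert_that(length(pred) == length(truth) && length(pred) > 0,
              "pred/truth must be equal-length and non-empty")
  if (is.null(classes)) classes <- sort(unique(c(pred, truth)))
  cm <- table(factor(truth, classes), factor(pred, classes))
  n <- sum(cm)
  per <- data.frame(class = classes, tp = 0, tn = 0, fp = 0, fn = 0,
                    accuracy = 0, recall = 0, precision = 0, f1 = 0)
  for (i in seq_along(classes)) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- n - tp - fn - fp
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1 <- if (pre + rec > 0) 2 * pre * rec / (pre + rec) else 0
    per[i, 2:9] <- c(tp, tn, fp, fn, (tp + tn) / n, rec, pre, f1)
  }
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / n,
                 macro_accuracy = mean(per$accuracy),
                 recall = mean(per$recall),
                 precision = mean(per$precision),
                 f1 = mean(per$f1),
                 per_class = per, n = n),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d accuracy=%.4f macro P/R/F1 = %.4f/%.4f/%.4f\n",
              x$n, x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Deterministic recording-level fold assignment
#'
#' @param n number of recordings. @param folds fold count. @param seed seed.
#' @return integer fold id per recording (a true partition).
#' @export
make_folds <- function(n, folds, seed = 1) {
  assert_that(n >= folds, "fewer recordings (%d) than folds (%d)", n, folds)
  ord <- with_seed(derive_seed(seed, "folds"), sample(n))
  fold <- integer(n)
  fold[ord] <- rep_len(seq_len(folds), n)
  fold
}

#' Recording-level cross-validation of the RNN on code sequences
#'
#' Recordings are partitioned into folds (no segment of a recording appears
#' in both train and test); one RNN is trained per fold and the test
#' confusions are pooled.
#'
#' @param sequences list of per-recording T_i x d code sequences.
#' @param labels list of per-step label vectors.
#' @param cfg an [rnn_config()]. @param folds fold count. @param seed fold
#'   assignment seed.
#' @return an `eval_report` with an extra `fold_scores` element (per-fold
#'   accuracies) and `fold_assign`.
#' @export
cross_validate <- function(sequences, labels, cfg = rnn_config(), folds = 10,
                           seed = 1) {
  n <- length(sequences)
  fold <- make_folds(n, folds, seed)
  classes <- sort(unique(unlist(labels)))
  preds <- character(0); truths <- character(0)
  fold_scores <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    model <- rnn_train(sequences[tr], labels[tr], cfg, classes = classes)
    fp <- character(0); ft <- character(0)
    for (i in te) {
      pr <- rnn_predict(model, sequences[[i]])
      fp <- c(fp, pr$labels); ft <- c(ft, labels[[i]])
    }
    preds <- c(preds, fp); truths <- c(truths, ft)
    fold_scores[f] <- mean(fp == ft)
  }
  rep <- evaluate_predictions(preds, truths, classes)
  rep$fold_scores <- fold_scores
  rep$fold_assign <- fold
  rep
}
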