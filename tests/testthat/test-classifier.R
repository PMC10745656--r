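test_that("analytic BPTT gradients match central finite differences", {
  cfg <- rnn_config(hidden_size = 3, seed = 0)
  params <- mmhar:::rnn_init(4, 2, cfg)
  X <- with_seed_test(0, matrix(rnorm(8), 2, 4))
  y <- c(1L, 2L)
  lg <- rnn_loss_grad(params, X, y)
  worst <- 0
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + 1e-5
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - 1e-5
      num <- (rnn_loss_grad(pp, X, y)$loss - rnn_loss_grad(pm, X, y)$loss) / 2e-5
      ana <- lg$grads[[nm]][i]
      rel <- abs(num - ana) / max(1e-8, abs(num) + abs(ana))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("training reaches 99% accuracy on separable sequences", {
  dat <- separable_data()
  cfg <- rnn_config(hidden_size = 8, epochs = 100, lr = 0.05, seed = 1)
  model <- rnn_train(dat$seqs, dat$labs, cfg)
  correct <- 0; total <- 0
  for (i in seq_along(dat$seqs)) {
    pr <- rnn_predict(model, dat$seqs[[i]])
    correct <- correct + sum(pr$labels == dat$labs[[i]])
    total <- total + length(dat$labs[[i]])
  }
  expect_gte(correct / total, 0.99)
  # loss decreased over training
  expect_lt(tail(model$loss_trace, 1), model$loss_trace[1])
})

test_that("permuted labels score at chance over cross-validation folds", {
  dat <- separable_data(n_seq = 60, seed = 51)
  labs <- with_seed_test(52, {
    pool <- unlist(dat$labs)
    shuffled <- sample(pool)
    split_idx <- rep(seq_along(dat$labs), lengths(dat$labs))
    split(shuffled, split_idx)
  })
  cfg <- rnn_config(hidden_size = 8, epochs = 30, lr = 0.05, seed = 2)
  rep <- cross_validate(dat$seqs, labs, cfg, folds = 10, seed = 3)
  n <- rep$n
  se <- sqrt(0.5 * 0.5 / n)
  expect_lt(abs(rep$accuracy - 0.5), 3 * se + 1e-12)
})

test_that("prediction is deterministic with valid probability rows", {
  dat <- separable_data(n_seq = 20, seed = 53)
  cfg <- rnn_config(hidden_size = 6, epochs = 10, lr = 0.05, seed = 4)
  model <- rnn_train(dat$seqs, dat$labs, cfg)
  p1 <- rnn_predict(model, dat$seqs[[1]])
  p2 <- rnn_predict(model, dat$seqs[[1]])
  expect_identical(p1, p2)
  expect_equal(rowSums(p1$probs), rep(1, nrow(p1$probs)), tolerance = 1e-9)
  expect_error(rnn_predict(model, matrix(0, 3, 7)), "dim")
})

test_that("a zero learning rate leaves the weights untouched", {
  dat <- separable_data(n_seq = 10, seed = 54)
  cfg <- rnn_config(hidden_size = 5, epochs = 3, lr = 0, seed = 5,
                    patience = 100)
  model <- rnn_train(dat$seqs, dat$labs, cfg)
  init <- mmhar:::rnn_init(4, 2, cfg)
  expect_identical(model$params, init)
})

test_that("metrics follow the one-vs-rest counting identities", {
  # perfect predictions
  r <- evaluate_predictions(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(r$accuracy, 1); expect_equal(r$f1, 1)
  expect_equal(r$precision, 1); expect_equal(r$recall, 1)
  # binary hand-computed case: TP=8 FN=2 FP=1 TN=9 for class "p"
  truth <- c(rep("p", 10), rep("n", 10))
  pred <- c(rep("p", 8), rep("n", 2), "p", rep("n", 9))
  r2 <- evaluate_predictions(pred, truth)
  pc <- r2$per_class[r2$per_class$class == "p", ]
  expect_equal(pc$tp, 8); expect_equal(pc$fn, 2)
  expect_equal(pc$fp, 1); expect_equal(pc$tn, 9)
  expect_equal(pc$accuracy, 0.85)
  expect_equal(pc$recall, 0.8)
  expect_equal(pc$precision, 8 / 9)
  expect_equal(pc$f1, 2 * (0.8 * 8 / 9) / (0.8 + 8 / 9), tolerance = 1e-12)
  # constant predictions on balanced binary data: macro recall 0.5
  r3 <- evaluate_predictions(rep("a", 20), c(rep("a", 10), rep("b", 10)))
  expect_equal(r3$recall, 0.5)
  expect_equal(r3$per_class$f1[r3$per_class$class == "b"], 0)
  # random confusion matrices against a brute-force counting oracle
  set.seed(17)
  classes <- c("w", "x", "y")
  for (i in 1:5) {
    truth <- sample(classes, 60, replace = TRUE)
    pred <- sample(classes, 60, replace = TRUE)
    r4 <- evaluate_predictions(pred, truth, classes)
    expect_equal(r4$accuracy, mean(pred == truth), tolerance = 1e-12)
    expect_equal(sum(r4$confusion), 60)
    for (cl in classes) {
      tp <- sum(pred == cl & truth == cl)
      fp <- sum(pred == cl & truth != cl)
      fn <- sum(pred != cl & truth == cl)
      rec <- if (tp + fn > 0) tp / (tp + fn) else 0
      pre <- if (tp + fp > 0) tp / (tp + fp) else 0
      row <- r4$per_class[r4$per_class$class == cl, ]
      expect_equal(row$recall, rec, tolerance = 1e-12)
      expect_equal(row$precision, pre, tolerance = 1e-12)
      expect_true(row$f1 >= min(pre, rec) - 1e-12 &&
                    row$f1 <= max(pre, rec) + 1e-12)
    }
  }
  expect_error(evaluate_predictions(character(0), character(0)), "non-empty")
})

test_that("fold assignment is a deterministic recording-level partition", {
  f1 <- make_folds(20, 10, seed = 2)
  f2 <- make_folds(20, 10, seed = 2)
  expect_identical(f1, f2)
  expect_equal(unname(table(f1)), rep(2L, 10), ignore_attr = TRUE)
  expect_false(identical(f1, make_folds(20, 10, seed = 3)))
  expect_error(make_folds(5, 10), "fewer recordings")
  expect_error(rnn_train(list(matrix(0, 2, 2)), list(c("a", "a"))),
               "2 classes")
})
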