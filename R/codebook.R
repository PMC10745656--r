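# Gaussian mixture codebook: EM fitting, responsibilities, Gaussian mixture
# regression, and per-segment encoding.

# log N(x; mu, Sigma) for rows of X, via Cholesky
gauss_logpdf <- function(X, mu, sigma) {
  d <- length(mu)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) stopf("covariance not positive definite beyond ridge")
  centered <- sweep(X, 2, mu, `-`)
  z <- forwardsolve(t(ch), t(centered))
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * d * log(2 * pi)
}

# k-means++ centre selection (seeded)
kmeanspp_centers <- function(X, K, seed) {
  n <- nrow(X)
  with_seed(seed, {
    centers <- matrix(0, K, ncol(X))
    idx <- sample.int(n, 1)
    centers[1, ] <- X[idx, ]
    if (K > 1) {
      d2 <- rowSums(sweep(X, 2, centers[1, ], `-`)^2)
      for (k in 2:K) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        idx <- sample.int(n, 1, prob = p)
        centers[k, ] <- X[idx, ]
        d2 <- pmin(d2, rowSums(sweep(X, 2, centers[k, ], `-`)^2))
      }
    }
    centers
  })
}

#' Fit a Gaussian mixture model by EM
#'
#' k-means++ initialization from an explicit seed, then alternating
#' responsibilities (E-step) and weight/mean/covariance updates (M-step;
#' covariances use the freshly updated means and are ridge-regularized) until
#' the log-likelihood improves by less than `tol` or `max_iter` is reached.
#' A component whose weight collapses below 1e-8 is re-seeded once at a
#' random data point; a second collapse is an error.
#'
#' @param X n x d descriptor matrix (n >= K, finite).
#' @param K number of components.
#' @param max_iter,tol EM stopping rule. @param ridge added to covariance
#'   diagonals. @param seed initialization seed.
#' @return a `gmm_model`: `K`, `weights`, `means` (K x d), `covs` (list of
#'   d x d), `loglik_trace` (non-decreasing), `d`.
#' @export
gmm_fit <- function(X, K, max_iter = 200, tol = 1e-6, ridge = 1e-6, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  assert_that(all(is.finite(X)), "X contains non-finite values")
  assert_that(K >= 1 && K <= n, "need 1 <= K <= n (K=%d, n=%d)", K, n)
  centers <- kmeanspp_centers(X, K, seed)
  assign <- apply(vapply(seq_len(K), function(k) {
    rowSums(sweep(X, 2, centers[k, ], `-`)^2)
  }, numeric(n)), 1, which.min)
  global_cov <- stats::cov(X) + ridge * diag(d)
  if (n == 1) global_cov <- ridge * diag(d)
  weights <- numeric(K); means <- matrix(0, K, d); covs <- vector("list", K)
  for (k in seq_len(K)) {
    rows <- which(assign == k)
    weights[k] <- max(length(rows), 1) / n
    means[k, ] <- if (length(rows)) colMeans(X[rows, , drop = FALSE]) else centers[k, ]
    covs[[k]] <- if (length(rows) >= 2) {
      stats::cov(X[rows, , drop = FALSE]) + ridge * diag(d)
    } else global_cov
  }
  weights <- weights / sum(weights)

  trace <- numeric(0)
  reseeded <- logical(K)
  prev_ll <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- vapply(seq_len(K), function(k) {
      log(weights[k]) + gauss_logpdf(X, means[k, ], covs[[k]])
    }, numeric(n))
    lp <- matrix(lp, n, K)
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    if (any(nk / n < 1e-8)) {
      bad <- which(nk / n < 1e-8)
      for (k in bad) {
        if (reseeded[k]) stopf("component %d collapsed twice", k)
        reseeded[k] <- TRUE
        j <- with_seed(derive_seed(seed, paste0("reseed", k, it)),
                       sample.int(n, 1))
        means[k, ] <- X[j, ]
        covs[[k]] <- global_cov
        weights[k] <- 1 / K
      }
      weights <- weights / sum(weights)
      prev_ll <- -Inf
      next
    }
    weights <- nk / n
    for (k in seq_len(K)) {
      means[k, ] <- colSums(resp[, k] * X) / nk[k]
      centered <- sweep(X, 2, means[k, ], `-`)
      covs[[k]] <- crossprod(centered * sqrt(resp[, k])) / nk[k] +
        ridge * diag(d)
    }
    if (is.finite(prev_ll) && ll - prev_ll < tol) break
    prev_ll <- ll
  }
  structure(list(K = K, d = d, weights = weights, means = means, covs = covs,
                 loglik_trace = trace, ridge = ridge, seed = seed),
            class = "gmm_model")
}

#' Posterior responsibilities of a fitted GMM
#'
#' @param model a `gmm_model`. @param X n x d matrix.
#' @return n x K matrix; rows sum to 1.
#' @export
gmm_responsibilities <- function(model, X) {
  X <- as.matrix(X)
  assert_that(ncol(X) == model$d, "dimension mismatch: %d vs model %d",
              ncol(X), model$d)
  n <- nrow(X)
  lp <- vapply(seq_len(model$K), function(k) {
    log(model$weights[k]) + gauss_logpdf(X, model$means[k, ], model$covs[[k]])
  }, numeric(n))
  lp <- matrix(lp, n, model$K)
  mx <- apply(lp, 1, max)
  exp(lp - (mx + log(rowSums(exp(lp - mx)))))
}

#' Gaussian mixture regression
#'
#' Conditional mean of the output dimensions given the input dimensions under
#' a fitted GMM: at each query point the per-component affine predictions
#' mu_O + Sigma_OI Sigma_II^-1 (x - mu_I) are blended with the input-marginal
#' responsibilities h_k. With K = 1 this is exactly the linear-Gaussian
#' regression closed form.
#'
#' @param model a `gmm_model`.
#' @param input_dims,output_dims disjoint index sets covering distinct model
#'   dimensions.
#' @param query matrix (or vector) of query points, one row per query, columns
#'   matching `input_dims`.
#' @return matrix of conditional means (queries x output dims).
#' @export
gmr_generalize <- function(model, input_dims, output_dims, query) {
  assert_that(length(intersect(input_dims, output_dims)) == 0,
              "input and output dims must be disjoint")
  assert_that(all(c(input_dims, output_dims) %in% seq_len(model$d)),
              "dims outside the model dimensionality")
  query <- if (is.null(dim(query))) {
    matrix(query, ncol = length(input_dims))
  } else as.matrix(query)
  K <- model$K
  nq <- nrow(query)
  pred <- array(0, c(nq, length(output_dims), K))
  logh <- matrix(0, nq, K)
  for (k in seq_len(K)) {
    muI <- model$means[k, input_dims]
    muO <- model$means[k, output_dims]
    SII <- model$covs[[k]][input_dims, input_dims, drop = FALSE]
    SOI <- model$covs[[k]][output_dims, input_dims, drop = FALSE]
    ch <- tryCatch(chol(SII), error = function(e) NULL)
    if (is.null(ch)) stopf("singular input-marginal covariance in component %d", k)
    logh[, k] <- log(model$weights[k]) + gauss_logpdf(query, muI, SII)
    diffs <- sweep(query, 2, muI, `-`)
    gain <- SOI %*% chol2inv(ch)
    pred[, , k] <- sweep(diffs %*% t(gain), 2, muO, `+`)
  }
  mx <- apply(logh, 1, max)
  h <- exp(logh - (mx + log(rowSums(exp(logh - mx)))))
  out <- matrix(0, nq, length(output_dims))
  for (k in seq_len(K)) out <- out + h[, k] * pred[, , k, drop = FALSE][, , 1]
  out
}

#' Encode descriptor sets against a fitted codebook
#'
#' Per segment: the soft-assignment histogram (column sums of the
#' responsibilities of the segment's descriptors; it sums to the number of
#' descriptors encoded, and is zero for an empty set) concatenated, when a
#' GMR query specification is given, with the GMR conditional mean evaluated
#' at the segment's query points. A query row of NA yields the unconditioned
#' mixture mean of the output dimensions.
#'
#' @param model a `gmm_model` fitted on this descriptor family.
#' @param desc_list list (one entry per segment) of descriptor matrices
#'   (rows = descriptors) or NULL/empty for segments with none.
#' @param input_dims,output_dims,query_list optional GMR spec;
#'   `query_list[[i]]` holds segment i's query points.
#' @return list of numeric code vectors, all the same length.
#' @export
encode_segments <- function(model, desc_list, input_dims = NULL,
                            output_dims = NULL, query_list = NULL) {
  out <- vector("list", length(desc_list))
  uncond <- if (!is.null(output_dims)) {
    as.numeric(model$weights %*% model$means[, output_dims, drop = FALSE])
  } else NULL
  for (i in seq_along(desc_list)) {
    D <- desc_list[[i]]
    hist <- if (is.null(D) || NROW(D) == 0) {
      rep(0, model$K)
    } else {
      D <- if (is.null(dim(D))) matrix(D, nrow = 1) else as.matrix(D)
      assert_that(ncol(D) == model$d, "descriptor dim %d != model dim %d",
                  ncol(D), model$d)
      colSums(gmm_responsibilities(model, D))
    }
    code <- hist
    if (!is.null(input_dims)) {
      q <- query_list[[i]]
      q <- if (is.null(dim(q))) matrix(q, ncol = length(input_dims)) else q
      gm <- matrix(0, nrow(q), length(output_dims))
      for (r in seq_len(nrow(q))) {
        gm[r, ] <- if (anyNA(q[r, ])) uncond else
          gmr_generalize(model, input_dims, output_dims, q[r, , drop = FALSE])
      }
      code <- c(code, as.numeric(t(gm)))
    }
    out[[i]] <- unname(code)
  }
  out
}
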