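# Discrete wavelet transform (orthogonal filter bank) with soft-threshold
# denoising. Periodic signal extension is used so the orthonormal filters give
# exact perfect reconstruction at every level.

# Daubechies-4 (two vanishing moments) analysis low-pass
DB4_LO <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
DB4_HI <- rev(DB4_LO) * c(1, -1, 1, -1)

HAAR_LO <- c(1, 1) / sqrt(2)
HAAR_HI <- c(1, -1) / sqrt(2)

wavelet_filters <- function(name) {
  switch(name,
         db4 = list(lo = DB4_LO, hi = DB4_HI),
         haar = list(lo = HAAR_LO, hi = HAAR_HI),
         stopf("unknown wavelet '%s' (supported: db4, haar)", name))
}

# One analysis level with periodic extension; x may have odd length, in which
# case the last sample is repeated (recorded by the caller via lengths).
dwt_step <- function(x, f) {
  if (length(x) %% 2 == 1) x <- c(x, x[length(x)])
  n <- length(x)
  L <- length(f$lo)
  idx <- outer(seq(1, n, by = 2) - 1, 0:(L - 1), `+`) %% n + 1
  xm <- matrix(x[idx], ncol = L)
  list(approx = as.numeric(xm %*% f$lo), detail = as.numeric(xm %*% f$hi))
}

idwt_step <- function(approx, detail, f, out_len) {
  n <- 2 * length(approx)
  L <- length(f$lo)
  x <- numeric(n)
  for (k in seq_along(approx)) {
    pos <- ((2 * (k - 1) + 0:(L - 1)) %% n) + 1
    x[pos] <- x[pos] + f$lo * approx[k] + f$hi * detail[k]
  }
  x[seq_len(out_len)]
}

#' Multilevel discrete wavelet transform
#'
#' @param x numeric series. @param wavelet "db4" or "haar".
#' @param level decomposition depth (>= 1).
#' @return list with `approx` (coarsest approximation), `details` (list,
#'   finest first) and the per-level input lengths needed for reconstruction.
#' @export
dwt_forward <- function(x, wavelet = "db4", level = 3) {
  assert_that(level >= 1, "level must be >= 1")
  assert_that(length(x) >= 2^level,
              "series of length %d too short for %d levels", length(x), level)
  f <- wavelet_filters(wavelet)
  details <- vector("list", level)
  lengths <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    lengths[l] <- length(a)
    st <- dwt_step(a, f)
    details[[l]] <- st$detail
    a <- st$approx
  }
  list(approx = a, details = details, lengths = lengths, wavelet = wavelet)
}

#' @rdname dwt_forward
#' @param dec a decomposition from [dwt_forward()].
#' @export
dwt_inverse <- function(dec) {
  f <- wavelet_filters(dec$wavelet)
  a <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[l]], f, dec$lengths[l])
  }
  a
}

#' Wavelet denoising by universal soft thresholding
#'
#' Decomposes `x`, soft-thresholds every detail band at the universal
#' threshold sigma * sqrt(2 log n) with sigma estimated from the finest
#' details (MAD / 0.6745), and reconstructs.
#'
#' @param x numeric series (length >= 2^level).
#' @param cfg a [filter_config()] supplying `wavelet_name` and `dwt_level`.
#' @return denoised series, same length as `x`.
#' @export
dwt_denoise <- function(x, cfg = filter_config()) {
  assert_that(length(x) >= 2^cfg$dwt_level,
              "series of length %d too short for dwt_level %d",
              length(x), cfg$dwt_level)
  dec <- dwt_forward(x, cfg$wavelet_name, cfg$dwt_level)
  sigma <- stats::median(abs(dec$details[[1]])) / 0.6745
  if (sigma == 0) return(dwt_inverse(dec))
  thr <- sigma * sqrt(2 * log(length(x)))
  soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
  dec$details <- lapply(dec$details, soft)
  dwt_inverse(dec)
}

# Single-level 2-D DWT soft-threshold denoise (Haar), used on video frames.
dwt2_denoise <- function(img) {
  f <- wavelet_filters("haar")
  H <- nrow(img); W <- ncol(img)
  rows_lo <- t(apply(img, 1, function(r) dwt_step(r, f)$approx))
  rows_hi <- t(apply(img, 1, function(r) dwt_step(r, f)$detail))
  ll <- apply(rows_lo, 2, function(col) dwt_step(col, f)$approx)
  lh <- apply(rows_lo, 2, function(col) dwt_step(col, f)$detail)
  hl <- apply(rows_hi, 2, function(col) dwt_step(col, f)$approx)
  hh <- apply(rows_hi, 2, function(col) dwt_step(col, f)$detail)
  sigma <- stats::median(abs(hh)) / 0.6745
  if (sigma > 0) {
    thr <- sigma * sqrt(2 * log(H * W))
    soft <- function(d) sign(d) * pmax(abs(d) - thr, 0)
    lh <- soft(lh); hl <- soft(hl); hh <- soft(hh)
  }
  wc <- ceiling(W / 2)
  rec_lo <- apply(rbind(ll, lh), 2, function(col) {
    idwt_step(col[seq_len(length(col) / 2)],
              col[-seq_len(length(col) / 2)], f, H)
  })
  rec_hi <- apply(rbind(hl, hh), 2, function(col) {
    idwt_step(col[seq_len(length(col) / 2)],
              col[-seq_len(length(col) / 2)], f, H)
  })
  t(apply(cbind(rec_lo, rec_hi), 1, function(r) {
    idwt_step(r[seq_len(wc)], r[-seq_len(wc)], f, W)
  }))
}
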