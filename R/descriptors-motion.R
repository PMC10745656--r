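#' Gaussian Markov random field window descriptor
#'
#' Per-channel sample means and the unbiased (n-1) cross-channel covariance
#' matrix of a multichannel window, vectorized as the mean vector followed by
#' the upper triangle (including the diagonal) of the covariance.
#'
#' @param x n x C matrix: one motion window, channels in columns.
#' @return a `gmrf_descriptor`: `mu` (length C), `sigma` (C x C), and
#'   `vectorized` (length C + C(C+1)/2).
#' @export
gmrf_descriptor <- function(x) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "need at least 2 samples per channel")
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  structure(list(mu = mu, sigma = sigma,
                 vectorized = c(mu, sigma[upper.tri(sigma, diag = TRUE)])),
            class = "gmrf_descriptor")
}

#' Short-time Fourier transform
#'
#' One-sided STFT with a rectangular (default) or Hann window.
#'
#' @param x numeric series. @param T window length in samples (>= 4).
#' @param hop hop size in samples. @param sample_rate Hz.
#' @param window "rect" or "hann".
#' @return list with complex `coef` (frames x bins), `freqs` (Hz),
#'   `times` (s, frame centres), `T`, `hop`, `sample_rate`.
#' @export
stft <- function(x, T, hop = T %/% 4, sample_rate = 1, window = "rect") {
  assert_that(T >= 4, "window length T must be >= 4")
  assert_that(T <= length(x), "T exceeds the series length")
  win <- switch(window, rect = rep(1, T),
                hann = 0.5 - 0.5 * cos(2 * pi * (0:(T - 1)) / (T - 1)),
                stopf("unknown window '%s'", window))
  starts <- seq(1, length(x) - T + 1, by = hop)
  nb <- T %/% 2 + 1
  # pad one sample so the one-sample-shifted frame exists for every window
  xp <- c(x, x[length(x)])
  frame_fft <- function(s) stats::fft(xp[s:(s + T - 1)] * win)[seq_len(nb)]
  coef <- t(vapply(starts, frame_fft, complex(nb)))
  # shifted frames give an alias-free phase advance per sample, from which
  # the instantaneous frequency is read during reassignment
  coef_next <- t(vapply(starts + 1, frame_fft, complex(nb)))
  list(coef = coef, coef_next = coef_next,
       freqs = (0:(nb - 1)) * sample_rate / T,
       times = (starts - 1 + T / 2) / sample_rate,
       T = T, hop = hop, sample_rate = sample_rate)
}

#' Short-time periodogram
#'
#' p(s, f) = |Y(s, f)|^2 / T for each time frame s and frequency bin f.
#'
#' @param x numeric series. @param T window length in samples (>= 4).
#' @param hop,sample_rate,window passed to [stft()].
#' @return frames x bins matrix of power values.
#' @export
periodogram <- function(x, T, hop = T %/% 4, sample_rate = 1, window = "rect") {
  st <- stft(x, T, hop, sample_rate, window)
  Mod(st$coef)^2 / T
}

#' Multisynchrosqueezing reassignment
#'
#' Squeezes STFT energy along the frequency axis: each coefficient's energy is
#' moved to the bin nearest its instantaneous-frequency estimate (the phase
#' advance of the STFT over one sample, alias-free below Nyquist), and the
#' bin-to-bin reassignment map is iterated `M` times (the method caps at two
#' iterations). Coefficients with magnitude below `guard` are left in place.
#' Total energy is conserved exactly; `M = 0` returns the raw energy matrix
#' unchanged.
#'
#' @param st an [stft()] result.
#' @param M number of reassignment iterations (0, 1 or 2 by default;
#'   `max_M` can raise the cap).
#' @param guard magnitude below which a coefficient is not moved.
#' @param max_M upper bound on `M`.
#' @return frames x bins matrix of reassigned energy (|Y|^2 units).
#' @export
msst <- function(st, M = 2, guard = 1e-12, max_M = 2) {
  assert_that(M >= 0 && M <= max_M, "M must lie in [0, %d]", max_M)
  energy <- Mod(st$coef)^2
  if (M == 0 || sum(energy) == 0) return(energy)
  co <- st$coef
  nt <- nrow(co); nb <- ncol(co)
  df <- st$sample_rate / st$T
  # instantaneous frequency per coefficient (Hz): phase advance over one
  # sample, f = Arg(Y_next conj(Y)) * fs / (2 pi), unambiguous below Nyquist
  target <- matrix(rep(seq_len(nb), each = nt), nt, nb)
  ok <- Mod(co) >= guard
  omega <- matrix(NA_real_, nt, nb)
  omega[ok] <- Arg(st$coef_next[ok] * Conj(co[ok])) * st$sample_rate / (2 * pi)
  tgt <- round(omega / df) + 1
  tgt[!ok | is.na(tgt)] <- target[!ok | is.na(tgt)]
  target <- pmin(pmax(tgt, 1), nb)
  # iterate the per-frame bin map; energy rides along with its coefficient
  pos <- matrix(rep(seq_len(nb), each = nt), nt, nb)
  for (m in seq_len(M)) {
    pos <- matrix(target[cbind(rep(seq_len(nt), nb), as.vector(pos))], nt, nb)
  }
  out <- matrix(0, nt, nb)
  for (s in seq_len(nt)) {
    for (b in seq_len(nb)) {
      out[s, pos[s, b]] <- out[s, pos[s, b]] + energy[s, b]
    }
  }
  out
}

#' Spatial-temporal frequency graph
#'
#' Six frequency-band nodes weighted by total (reassigned) energy, with edge
#' weights given by temporal co-activation: the fraction of time frames in
#' which both bands are simultaneously strictly above their own median band
#' energy.
#'
#' @param energy frames x bins energy matrix (e.g. from [msst()]).
#' @param freqs bin frequencies (Hz), length = ncol(energy).
#' @param band_edges strictly increasing vector of 7 edges covering the
#'   frequency range (6 bands). Default: equal-width partition of
#'   [0, max(freqs)].
#' @return an `st_graph` object: `nodes` (band centres, Hz), `node_energy`
#'   (length 6), `edges` (6 x 6 symmetric weight matrix, zero diagonal) and
#'   `vectorized` (energies then upper-triangle weights, length 21).
#' @export
st_graph <- function(energy, freqs, band_edges = NULL) {
  nb <- 6
  if (is.null(band_edges)) {
    band_edges <- seq(0, max(freqs), length.out = nb + 1)
  }
  assert_that(length(band_edges) == nb + 1,
              "need exactly %d band edges for %d bands", nb + 1, nb)
  assert_that(all(diff(band_edges) > 0), "band edges must be increasing")
  band <- findInterval(freqs, band_edges, rightmost.closed = TRUE)
  band[band < 1] <- 1; band[band > nb] <- nb
  be <- vapply(seq_len(nb), function(i) {
    cols <- which(band == i)
    if (!length(cols)) rep(0, nrow(energy)) else
      rowSums(energy[, cols, drop = FALSE])
  }, numeric(nrow(energy)))
  be <- matrix(be, nrow = nrow(energy))
  node_energy <- colSums(be)
  med <- apply(be, 2, stats::median)
  # a band only counts as active above its median if it also carries
  # non-negligible energy (guards against spectral-leakage dust)
  active <- sweep(be, 2, med, `>`) & (be > 1e-6 * max(be))
  W <- crossprod(active * 1) / nrow(be)
  diag(W) <- 0
  structure(list(nodes = (band_edges[-1] + band_edges[-(nb + 1)]) / 2,
                 node_energy = node_energy, edges = W,
                 vectorized = c(node_energy, W[upper.tri(W)])),
            class = "st_graph")
}

#' Rebuild node energies and edge weights from a vectorized st_graph
#'
#' Inverse of the fixed-order flattening used by [st_graph()] (bijective for
#' a fixed band count).
#'
#' @param v numeric vector of length 21 (6 energies + 15 edge weights).
#' @param n_bands band count the vector was built with.
#' @return list with `node_energy` and `edges`.
#' @export
st_graph_unvectorize <- function(v, n_bands = 6) {
  assert_that(length(v) == n_bands + n_bands * (n_bands - 1) / 2,
              "wrong vector length for %d bands", n_bands)
  node_energy <- v[seq_len(n_bands)]
  W <- matrix(0, n_bands, n_bands)
  W[upper.tri(W)] <- v[-seq_len(n_bands)]
  W <- W + t(W)
  list(node_energy = node_energy, edges = W)
}

#' Motion descriptors for one windowed segment
#'
#' Computes the GMRF descriptor over the window's channels and the MSST
#' spatial-temporal graph over its combined-norm series.
#'
#' @param channels n x C channel matrix for the window.
#' @param norm_series combined-magnitude series for the window.
#' @param sample_rate Hz. @param T STFT window (samples). @param M MSST
#'   iterations. @param graphs if FALSE (descriptor-ablation baseline), the
#'   graph part is replaced by per-channel mean/variance moments.
#' @return list with `gmrf` and `graph` descriptor vectors.
#' @export
motion_descriptors <- function(channels, norm_series, sample_rate,
                               T = 32, M = 2, graphs = TRUE) {
  g <- gmrf_descriptor(channels)
  if (graphs) {
    T <- min(T, length(norm_series))
    st <- stft(norm_series - mean(norm_series), T, hop = max(1, T %/% 4),
               sample_rate = sample_rate)
    sq <- msst(st, M)
    gr <- st_graph(sq, st$freqs)
    list(gmrf = g$vectorized, graph = gr$vectorized)
  } else {
    mom <- c(colMeans(channels), apply(channels, 2, stats::var),
             mean(norm_series), stats::var(norm_series))
    list(gmrf = g$vectorized, graph = unname(mom))
  }
}
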