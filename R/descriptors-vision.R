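#' Thermal motion map over a frame window
#'
#' Accumulates per-pixel absolute inter-frame differences ("heat"): more
#' movement gives higher heat. The scalar summary is TM = sum_i ln(1 + R_i)
#' over all heat values (the log1p form keeps zero-heat pixels finite;
#' `log_mode = "as_printed_ln"` uses a plain ln and masks zero pixels). An
#' 8 x 8 mean-pooled grid of the heat map is attached for descriptor use.
#'
#' @param frames list of >= 2 equally shaped frames.
#' @param log_mode "log1p" (default) or "as_printed_ln".
#' @return a `thermal_map`: `heat` (H x W, >= 0), `tm` (scalar), `pooled`
#'   (length 64) and `vectorized` = c(tm, pooled).
#' @export
thermal_map <- function(frames, log_mode = c("log1p", "as_printed_ln")) {
  log_mode <- match.arg(log_mode)
  assert_that(length(frames) >= 2, "need at least 2 frames")
  heat <- matrix(0, nrow(frames[[1]]), ncol(frames[[1]]))
  for (j in 2:length(frames)) {
    heat <- heat + abs(frames[[j]] - frames[[j - 1]])
  }
  tm <- if (log_mode == "log1p") {
    sum(log1p(heat))
  } else {
    sum(log(heat[heat > 0]))
  }
  pooled <- pool_grid(heat, 8, 8)
  structure(list(heat = heat, tm = tm, pooled = pooled,
                 vectorized = c(tm, pooled)),
            class = "thermal_map")
}

# Mean-pool a matrix onto an r x c grid (cells as equal as possible)
pool_grid <- function(m, r, c) {
  ri <- cut(seq_len(nrow(m)), r, labels = FALSE)
  ci <- cut(seq_len(ncol(m)), c, labels = FALSE)
  out <- matrix(0, r, c)
  for (i in seq_len(r)) {
    rows <- ri == i
    for (j in seq_len(c)) {
      out[i, j] <- mean(m[rows, ci == j])
    }
  }
  as.numeric(out)
}

#' Fit a generalized Gaussian distribution by moment matching
#'
#' The shape theta is recovered by inverting the generalized Gaussian moment
#' ratio r = E|f|^2 / (E|f|)^2 = Gamma(1/theta) Gamma(3/theta) /
#' Gamma(2/theta)^2 via bisection; the scale then follows from the closed
#' form E|f|^theta = sigma^theta / theta.
#'
#' @param x numeric samples (>= 50, not all equal).
#' @return a `ggd_params` list with `theta` and `sigma` (both > 0).
#' @export
fit_ggd <- function(x) {
  assert_that(length(x) >= 50, "need at least 50 samples")
  assert_that(stats::sd(x) > 0, "degenerate (constant) samples")
  a <- abs(x - 0)    # zero-mean model; callers centre their features
  r <- mean(a^2) / mean(a)^2
  ratio <- function(th) {
    exp(lgamma(1 / th) + lgamma(3 / th) - 2 * lgamma(2 / th))
  }
  lo <- 0.05; hi <- 50
  r <- min(max(r, ratio(hi) + 1e-12), ratio(lo) - 1e-12)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (ratio(mid) > r) lo <- mid else hi <- mid
  }
  theta <- (lo + hi) / 2
  sigma <- (theta * mean(a^theta))^(1 / theta)
  structure(list(theta = theta, sigma = sigma), class = "ggd_params")
}

# log-density of the GGD at x
ggd_logpdf <- function(x, p) {
  log(p$theta) - log(2 * p$sigma) - lgamma(1 / p$theta) -
    abs(x / p$sigma)^p$theta
}

# Multiscale band-pass feature stack: difference of Gaussian smoothings at
# three scales. DC-free by construction.
bandpass_channels <- function(frame, scales = c(1, 2, 4)) {
  blur <- function(img, s) {
    # brush must fit inside the frame
    r <- min(2 * ceiling(2 * s) + 1, min(dim(frame)) - 1)
    if (r %% 2 == 0) r <- r - 1
    EBImage::gblur(EBImage::Image(img), sigma = s, radius = r)
  }
  lapply(scales, function(s) {
    matrix(as.numeric(blur(frame, s) - blur(frame, 2 * s)),
           nrow(frame), ncol(frame))
  })
}

#' Fit the per-channel GGD bank for saliency
#'
#' @param frames list of frames the bank is calibrated on.
#' @param scales band-pass scales (pixels).
#' @return list of `ggd_params`, one per channel.
#' @export
fit_ggd_bank <- function(frames, scales = c(1, 2, 4)) {
  samples <- vector("list", length(scales))
  for (fr in frames) {
    ch <- bandpass_channels(fr, scales)
    for (i in seq_along(scales)) {
      samples[[i]] <- c(samples[[i]], as.numeric(ch[[i]]))
    }
  }
  lapply(samples, fit_ggd)
}

#' Saliency map from GGD feature likelihoods
#'
#' Rare band-pass responses are salient: salience(pixel) is the sum over
#' channels of the negative GGD log-likelihood of the pixel's feature value,
#' min-max normalized to [0, 1]. A constant salience field (e.g. a uniform
#' frame) returns the guard value 1e-9 everywhere.
#'
#' @param frame H x W image. @param ggd_bank from [fit_ggd_bank()].
#' @param scales must match the bank's scales.
#' @return H x W salience matrix in [0, 1].
#' @export
saliency_map <- function(frame, ggd_bank, scales = c(1, 2, 4)) {
  assert_that(length(ggd_bank) == length(scales),
              "ggd_bank does not match the channel definitions")
  ch <- bandpass_channels(frame, scales)
  sal <- matrix(0, nrow(frame), ncol(frame))
  for (i in seq_along(ch)) {
    sal <- sal - ggd_logpdf(ch[[i]], ggd_bank[[i]])
  }
  rng <- range(sal)
  if (diff(rng) < 1e-12) return(matrix(1e-9, nrow(frame), ncol(frame)))
  (sal - rng[1]) / diff(rng)
}

# Triangle catalogue: (a, vertex, b); the angle is measured at `vertex`
TRIANGLE_CATALOGUE <- list(
  c("shoulderL", "head", "shoulderR"),
  c("shoulderL", "elbowL", "wristL"),
  c("shoulderR", "elbowR", "wristR"),
  c("kneeL", "torso", "kneeR"),
  c("torso", "kneeL", "ankleL"),
  c("torso", "kneeR", "ankleR")
)

#' Skeleton orientation angles
#'
#' For each catalogued landmark triangle, the angle at the middle vertex
#' between the two sides, computed as atan2(||u x v||, u . v) — numerically
#' robust and equal to acos of the normalized dot product. Invariant to
#' global translation, rotation and uniform scaling of the skeleton.
#' Triangles with missing landmarks or zero-length sides yield NA.
#'
#' @param landmarks 12 x 2 matrix (rows named as in [skeleton_landmarks()]),
#'   or a `skeleton_points` object.
#' @return an `orientation_descriptor`: `angles` (length 6, radians in
#'   [0, pi], NA when degenerate) and `valid` flags.
#' @export
orientation_angles <- function(landmarks) {
  if (inherits(landmarks, "skeleton_points")) {
    landmarks <- skeleton_to_landmarks(landmarks)
  }
  angles <- rep(NA_real_, length(TRIANGLE_CATALOGUE))
  for (i in seq_along(TRIANGLE_CATALOGUE)) {
    tri <- TRIANGLE_CATALOGUE[[i]]
    if (any(!tri %in% rownames(landmarks))) next
    p <- landmarks[tri, , drop = FALSE]
    if (anyNA(p)) next
    u <- p[1, ] - p[2, ]
    v <- p[3, ] - p[2, ]
    nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
    if (nu == 0 || nv == 0) next
    angles[i] <- vec_angle(u, v)
  }
  structure(list(angles = angles, valid = !is.na(angles)),
            class = "orientation_descriptor")
}

#' Angle between two 2-D or 3-D vectors via atan2(||u x v||, u . v)
#' @param u,v numeric vectors of equal length (2 or 3).
#' @export
vec_angle <- function(u, v) {
  if (length(u) == 2) {
    cross <- abs(u[1] * v[2] - u[2] * v[1])
  } else {
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    cross <- sqrt(sum(cr^2))
  }
  atan2(cross, sum(u * v))
}

#' Spider local image feature (SLIF)
#'
#' Samples pixel intensities on a polar spiderweb of `N` spokes and `M` rings
#' centred at a skeleton point: node (n, m) sits at
#' point + (m * ring_step * cos(2 pi n / N), m * ring_step * sin(2 pi n / N))
#' in (row, col) coordinates. Intensities are bilinearly interpolated;
#' out-of-frame nodes are sampled as 0 and flagged. Vectorization is
#' row-major with the ring index outermost.
#'
#' @param frame H x W image. @param point c(row, col) centre.
#' @param N spokes (>= 3). @param M rings (>= 1). @param ring_step px.
#' @return a `slif_descriptor`: `nodes` ((N*M) x 2 coordinates), `samples`
#'   (length N*M), `outside` (logical flags).
#' @export
slif <- function(frame, point, N = 8, M = 3, ring_step = 2) {
  assert_that(N >= 3, "need at least 3 spokes")
  assert_that(M >= 1, "need at least 1 ring")
  angles <- 2 * pi * (0:(N - 1)) / N
  nodes <- matrix(0, N * M, 2)
  k <- 0
  for (m in seq_len(M)) {
    for (n in seq_len(N)) {
      k <- k + 1
      nodes[k, ] <- point + m * ring_step * c(cos(angles[n]), sin(angles[n]))
    }
  }
  samples <- numeric(N * M)
  outside <- logical(N * M)
  for (k in seq_len(N * M)) {
    s <- bilinear_sample(frame, nodes[k, 1], nodes[k, 2])
    if (is.na(s)) {
      outside[k] <- TRUE
      samples[k] <- 0
    } else {
      samples[k] <- s
    }
  }
  structure(list(nodes = nodes, samples = samples, outside = outside,
                 N = N, M = M, ring_step = ring_step),
            class = "slif_descriptor")
}

# Bilinear interpolation; NA outside the frame
bilinear_sample <- function(img, r, c) {
  if (r < 1 || c < 1 || r > nrow(img) || c > ncol(img)) return(NA_real_)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- min(r0 + 1, nrow(img)); c1 <- min(c0 + 1, ncol(img))
  fr <- r - r0; fc <- c - c0
  img[r0, c0] * (1 - fr) * (1 - fc) + img[r1, c0] * fr * (1 - fc) +
    img[r0, c1] * (1 - fr) * fc + img[r1, c1] * fr * fc
}

# SLIF key points used by the pipeline descriptor (distal limbs + head carry
# the activity signal)
SLIF_POINTS <- c("head", "wristL", "wristR", "ankleL", "ankleR")

#' Vision descriptors for a window of frames
#'
#' Thermal map over the window, pooled saliency of the middle frame,
#' orientation angles and SLIF web samples of the middle frame's skeleton.
#' Missing-landmark entries are encoded as 0.
#'
#' @param frames frames in the window. @param landmarks matching 12 x 2
#'   landmark matrices. @param ggd_bank saliency GGD bank.
#' @param slif_N,slif_M,slif_step SLIF web geometry.
#' @return list of family vectors: `thermal` (65), `saliency` (16),
#'   `orientation` (6), `slif` (length(SLIF_POINTS) * N * M).
#' @export
vision_descriptors <- function(frames, landmarks, ggd_bank,
                               slif_N = 6, slif_M = 2, slif_step = 2) {
  mid <- (length(frames) + 1) %/% 2
  th <- if (length(frames) >= 2) thermal_map(frames) else
    list(vectorized = c(0, rep(0, 64)))
  sal <- saliency_map(frames[[mid]], ggd_bank)
  sal_pooled <- pool_grid(sal, 4, 4)
  lm <- landmarks[[mid]]
  oa <- orientation_angles(lm)
  ang <- ifelse(is.na(oa$angles), 0, oa$angles)
  sl <- numeric(0)
  for (pt in SLIF_POINTS) {
    if (anyNA(lm[pt, ])) {
      sl <- c(sl, rep(0, slif_N * slif_M))
    } else {
      sl <- c(sl, slif(frames[[mid]], lm[pt, ], slif_N, slif_M,
                       slif_step)$samples)
    }
  }
  list(thermal = th$vectorized, saliency = sal_pooled,
       orientation = ang, slif = sl)
}
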