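#' Frame sequences
#'
#' A list of equally shaped grayscale frames (0-255 matrices) with a frame
#' rate and the sampling stride applied so far.
#'
#' @param frames list of H x W numeric matrices.
#' @param fps frames per second. @param stride sampling delta applied (>= 1).
#' @export
frame_sequence <- function(frames, fps, stride = 1) {
  assert_that(length(frames) > 0, "frame list is empty")
  dims <- vapply(frames, dim, numeric(2))
  assert_that(all(dims[1, ] == dims[1, 1]) && all(dims[2, ] == dims[2, 1]),
              "all frames must share one shape")
  assert_that(stride >= 1, "stride must be >= 1")
  structure(list(frames = frames, fps = fps, stride = stride),
            class = "frame_sequence")
}

#' Keep every delta-th frame
#'
#' Down-samples a frame sequence, keeping frames at indices 1, 1+delta,
#' 1+2*delta, ... and rescaling the fps metadata.
#'
#' @param fs a [frame_sequence()]. @param delta sampling step (>= 1).
#' @export
sample_frames <- function(fs, delta) {
  assert_that(inherits(fs, "frame_sequence"), "fs must be a frame_sequence")
  assert_that(delta >= 1, "delta must be >= 1")
  keep <- seq(1, length(fs$frames), by = delta)
  frame_sequence(fs$frames[keep], fps = fs$fps / delta,
                 stride = fs$stride * delta)
}

#' Per-pixel median background model
#'
#' @param fs a [frame_sequence()] with at least 3 frames.
#' @return H x W background image.
#' @export
background_model <- function(fs) {
  assert_that(inherits(fs, "frame_sequence"), "fs must be a frame_sequence")
  assert_that(length(fs$frames) >= 3, "need >= 3 frames for a background model")
  arr <- simplify2array(fs$frames)
  apply(arr, c(1, 2), stats::median)
}

#' Foreground mask by background subtraction
#'
#' Thresholds the absolute difference against the background and removes
#' speckle with a 3x3 morphological opening.
#'
#' @param frame H x W image. @param bg background image of the same shape.
#' @param thresh intensity threshold (> 0).
#' @param denoise apply single-level 2-D wavelet denoising to the frame first.
#' @return binary H x W matrix (0/1).
#' @export
subtract_background <- function(frame, bg, thresh = 50, denoise = FALSE) {
  assert_that(all(dim(frame) == dim(bg)), "frame/background shape mismatch")
  if (denoise) frame <- dwt2_denoise(frame)
  mask <- (abs(frame - bg) > thresh) * 1
  opened <- EBImage::opening(EBImage::Image(mask),
                             EBImage::makeBrush(3, shape = "box"))
  matrix(as.numeric(opened > 0.5), nrow(frame), ncol(frame))
}

# Vertical band limits (fractions of the figure bounding-box height) used to
# assign blob centroids to skeleton categories. The synthetic renderer places
# landmarks so that these bands are exact on noiseless fixtures.
SKELETON_BANDS <- list(
  head      = c(0.00, 0.12),
  shoulders = c(0.12, 0.25),
  elbows    = c(0.25, 0.40),
  wrists    = c(0.40, 0.52),
  torso     = c(0.25, 0.55),   # central column only
  knees     = c(0.55, 0.78),
  ankles    = c(0.78, 1.001)
)
SKELETON_EXPECTED <- c(head = 1, shoulders = 2, elbows = 2, wrists = 2,
                       torso = 1, knees = 2, ankles = 2)

#' Skeleton landmark extraction from a foreground mask
#'
#' Connected components of at least `min_area` pixels become blobs; blob
#' centroids are assigned to the 7 skeleton categories (head, shoulders,
#' elbows, wrists, torso, knees, ankles) by their normalized vertical position
#' within the mask bounding box, with a left/right split about the box's
#' vertical midline for paired categories and a central-column requirement for
#' the torso. Per-category confidence is the fraction of expected points
#' found. An empty mask yields an empty result with zero confidences, never an
#' error.
#'
#' @param mask binary H x W matrix. @param min_area minimum blob area (px).
#' @return a `skeleton_points` object: `points` (per category, a k x 2 matrix
#'   of (row, col) centroids, left before right) and `confidence`.
#' @export
extract_skeleton <- function(mask, min_area = 4) {
  empty <- structure(list(
    points = stats::setNames(vector("list", length(SKELETON_CATEGORIES)),
                             SKELETON_CATEGORIES),
    confidence = stats::setNames(rep(0, length(SKELETON_CATEGORIES)),
                                 SKELETON_CATEGORIES)),
    class = "skeleton_points")
  if (sum(mask) == 0) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  if (!length(keep)) return(empty)
  cent <- t(vapply(keep, function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    c(mean(px[, 1]), mean(px[, 2]))
  }, numeric(2)))
  rmin <- min(cent[, 1]); rmax <- max(cent[, 1])
  cmid <- (min(cent[, 2]) + max(cent[, 2])) / 2
  width <- max(cent[, 2]) - min(cent[, 2])
  h <- max(rmax - rmin, 1e-9)
  yn <- (cent[, 1] - rmin) / h
  central <- abs(cent[, 2] - cmid) <= pmax(0.15 * width, 1.5)

  pts <- empty$points
  conf <- empty$confidence
  band_center <- vapply(SKELETON_BANDS, mean, numeric(1))
  for (b in seq_along(yn)) {
    cands <- names(SKELETON_BANDS)[vapply(SKELETON_BANDS, function(bb) {
      yn[b] >= bb[1] && yn[b] < bb[2]
    }, logical(1))]
    if (!length(cands)) next
    # torso is the central-column category; lateral blobs in the overlapping
    # span go to the paired bands, ties broken by nearest band centre
    if ("torso" %in% cands) {
      cands <- if (central[b]) "torso" else setdiff(cands, "torso")
    }
    if (!length(cands)) next
    cat <- cands[which.min(abs(band_center[cands] - yn[b]))]
    pts[[cat]] <- rbind(pts[[cat]], cent[b, , drop = FALSE])
  }
  # enforce pairing: at most one point per side for paired categories
  for (cat in names(SKELETON_EXPECTED)) {
    p <- pts[[cat]]
    if (is.null(p)) next
    if (SKELETON_EXPECTED[[cat]] == 1) {
      if (nrow(p) > 1) {
        p <- p[which.min(abs((p[, 1] - rmin) / h - band_center[cat])), ,
               drop = FALSE]
      }
    } else {
      left <- p[p[, 2] < cmid, , drop = FALSE]
      right <- p[p[, 2] >= cmid, , drop = FALSE]
      pick <- function(m) {
        if (nrow(m) <= 1) return(m)
        m[which.min(abs((m[, 1] - rmin) / h - band_center[cat])), , drop = FALSE]
      }
      p <- rbind(pick(left), pick(right))
    }
    colnames(p) <- c("row", "col")
    pts[[cat]] <- p
    conf[[cat]] <- nrow(p) / SKELETON_EXPECTED[[cat]]
  }
  structure(list(points = pts, confidence = conf), class = "skeleton_points")
}

#' Total number of landmarks in a skeleton_points object
#' @param sk a `skeleton_points`.
#' @export
skeleton_count <- function(sk) {
  sum(vapply(sk$points, function(p) if (is.null(p)) 0L else nrow(p), integer(1)))
}

# Flatten a skeleton to a named landmark matrix matching the generator's
# layout (NA rows for missing points).
skeleton_to_landmarks <- function(sk) {
  lm <- matrix(NA_real_, 12, 2,
               dimnames = list(skeleton_landmarks(), c("row", "col")))
  singles <- c(head = "head", torso = "torso")
  for (cat in names(singles)) {
    p <- sk$points[[cat]]
    if (!is.null(p) && nrow(p) >= 1) lm[cat, ] <- p[1, ]
  }
  paired <- c(shoulders = "shoulder", elbows = "elbow", wrists = "wrist",
              knees = "knee", ankles = "ankle")
  for (cat in names(paired)) {
    p <- sk$points[[cat]]
    if (is.null(p) || nrow(p) == 0) next
    ord <- order(p[, 2])
    lm[paste0(paired[cat], "L"), ] <- p[ord[1], ]
    if (nrow(p) == 2) lm[paste0(paired[cat], "R"), ] <- p[ord[2], ]
  }
  lm
}

#' Run vision preprocessing over a recording
#'
#' Builds the median background, subtracts it from every (optionally strided)
#' frame and extracts skeleton points per frame.
#'
#' @param rec an `mm_recording`. @param delta frame sampling stride.
#' @param thresh subtraction threshold. @param denoise 2-D DWT denoise frames.
#' @return list with `frame_idx` (indices kept), `masks`, `skeletons`,
#'   `landmarks` (per frame 12 x 2, NA when missing), `bg`.
#' @export
preprocess_vision <- function(rec, delta = 1, thresh = 50, denoise = FALSE) {
  fs <- frame_sequence(rec$frames, rec$script$fps_video)
  sub <- sample_frames(fs, delta)
  keep <- seq(1, length(fs$frames), by = delta)
  bg <- background_model(sub)
  masks <- lapply(sub$frames, subtract_background, bg = bg, thresh = thresh,
                  denoise = denoise)
  skeletons <- lapply(masks, extract_skeleton)
  landmarks <- lapply(skeletons, skeleton_to_landmarks)
  list(frame_idx = keep, masks = masks, skeletons = skeletons,
       landmarks = landmarks, bg = bg)
}
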