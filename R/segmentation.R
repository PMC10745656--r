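#' Overlapped time-based windows
#'
#' Cuts a uniformly sampled stream into windows of `W` seconds with hop
#' `W * (1 - overlap)`; a trailing partial window is dropped. Each window is
#' labelled by the majority ground-truth label over its span (ties broken
#' toward the earlier label).
#'
#' @param n_samples number of samples in the stream.
#' @param sample_rate Hz. @param W window length, seconds.
#' @param overlap fraction in [0, 1). @param labels optional per-sample labels.
#' @param modality segment modality tag.
#' @return list of segments, each `list(modality, start_s, end_s, idx, label)`
#'   where `idx` are the 1-based sample indices; empty list when the stream is
#'   shorter than one window.
#' @export
window_segments <- function(n_samples, sample_rate, W = 2, overlap = 0.5,
                            labels = NULL, modality = "motion") {
  assert_that(W > 0, "W must be positive")
  assert_that(overlap >= 0 && overlap < 1, "overlap must lie in [0, 1)")
  wlen <- round(W * sample_rate)
  hop <- max(1L, round(wlen * (1 - overlap)))
  if (wlen > n_samples) return(list())
  starts <- seq(1L, n_samples - wlen + 1L, by = hop)
  lapply(starts, function(s) {
    idx <- s:(s + wlen - 1L)
    lab <- if (is.null(labels)) "none" else majority_label(labels[idx])
    list(modality = modality,
         start_s = (s - 1) / sample_rate,
         end_s = (s - 1 + wlen) / sample_rate,
         idx = idx, label = lab)
  })
}

# Majority label; ties broken toward the label occurring earliest in the span
majority_label <- function(labels) {
  if (!length(labels)) return("none")
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  labels[min(match(top, labels))]
}

#' Event-based segmentation of a frame sequence
#'
#' Places change-points where the smoothed mean inter-frame skeleton landmark
#' displacement crosses `thresh` (displacement >= thresh counts as motion);
#' contiguous spans between change-points become segments whose union covers
#' the whole sequence.
#'
#' @param landmarks list of per-frame 12 x 2 landmark matrices (NA allowed).
#' @param fps frames per second. @param thresh displacement threshold
#'   (pixels/frame). @param smooth centred moving-average width (frames).
#' @param labels optional per-frame labels.
#' @return list of vision segments with `idx` = frame indices and a `moving`
#'   flag; fewer than 2 frames yields an empty list.
#' @export
event_segments <- function(landmarks, fps, thresh = 0.5, smooth = 5,
                           labels = NULL) {
  nf <- length(landmarks)
  if (nf < 2) return(list())
  disp <- numeric(nf)
  for (j in 2:nf) {
    a <- landmarks[[j - 1]]; b <- landmarks[[j]]
    ok <- stats::complete.cases(a) & stats::complete.cases(b)
    disp[j] <- if (any(ok)) {
      mean(sqrt(rowSums((b[ok, , drop = FALSE] - a[ok, , drop = FALSE])^2)))
    } else 0
  }
  disp[1] <- disp[2]
  if (smooth > 1) {
    sm <- stats::filter(disp, rep(1 / smooth, smooth), sides = 2)
    disp <- ifelse(is.na(sm), disp, as.numeric(sm))
  }
  moving <- disp >= thresh   # tie: exactly at threshold counts as motion
  cp <- c(1, which(diff(moving) != 0) + 1, nf + 1)
  segs <- list()
  for (i in seq_len(length(cp) - 1)) {
    idx <- cp[i]:(cp[i + 1] - 1)
    lab <- if (is.null(labels)) "none" else majority_label(labels[idx])
    segs[[i]] <- list(modality = "vision",
                      start_s = (idx[1] - 1) / fps,
                      end_s = idx[length(idx)] / fps,
                      idx = idx, label = lab,
                      moving = moving[idx[1]])
  }
  segs
}
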