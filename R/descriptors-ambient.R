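#' Ambient sensor graph R = (M, K)
#'
#' Builds the descriptor matrix M (per-sensor type code, neighbour count and
#' mounting orientation) and the binary symmetric adjacency matrix K from an
#' [ambient_layout()]. Rows are ordered by sensor id; type codes are
#' switch = 0, PIR = 1, infrared = 2.
#'
#' @param layout an [ambient_layout()].
#' @return an `ambient_graph`: `M` (n x 3 matrix with columns type_code,
#'   n_neighbors, orientation), `K` (n x n 0/1 matrix) and `sensor_ids`.
#' @export
build_ambient_graph <- function(layout) {
  assert_that(inherits(layout, "ambient_layout"), "layout must be an ambient_layout")
  sensors <- layout$sensors
  ord <- order(sensors$sensor_id)
  sensors <- sensors[ord, , drop = FALSE]
  sensors$neighbors <- layout$sensors$neighbors[ord]
  ids <- sensors$sensor_id
  n <- length(ids)
  K <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (nb in sensors$neighbors[[i]]) K[i, match(nb, ids)] <- 1L
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      assert_that(K[i, j] == K[j, i],
                  "asymmetric neighbor lists for pair (%s, %s)", ids[i], ids[j])
    }
  }
  assert_that(all(diag(K) == 0), "a sensor cannot neighbour itself")
  type_code <- c(switch = 0, PIR = 1, infrared = 2)[sensors$sensor_type]
  M <- cbind(type_code = unname(type_code), n_neighbors = rowSums(K),
             orientation = sensors$orientation)
  rownames(M) <- ids
  structure(list(M = M, K = K, sensor_ids = ids), class = "ambient_graph")
}

#' Per-window ambient feature vector
#'
#' For a time window, counts 0 -> 1 transitions per sensor, sums per-sensor
#' active durations (an activation still open at the window end is truncated
#' there; one already open at the window start counts from the start), ranks
#' sensors by first activation, and counts the edges of K whose endpoints
#' both activate inside the window. Fixed length 3 * n_sensors + 1:
#' (counts, durations, first-activation rank with 0 = never active,
#' active-subgraph edge count).
#'
#' @param events data.frame (time_s, sensor_id, state), time-sorted.
#' @param graph an `ambient_graph` from [build_ambient_graph()].
#' @param start_s,end_s window bounds (seconds, end exclusive).
#' @return numeric feature vector.
#' @export
ambient_window_features <- function(events, graph, start_s, end_s) {
  assert_that(!is.unsorted(events$time_s), "events must be time-sorted")
  ids <- graph$sensor_ids
  n <- length(ids)
  counts <- durations <- first_t <- stats::setNames(numeric(n), ids)
  first_t[] <- Inf
  active_in_window <- stats::setNames(logical(n), ids)
  for (s in seq_len(n)) {
    ev <- events[events$sensor_id == ids[s], , drop = FALSE]
    if (!nrow(ev)) next
    # state entering the window
    prior <- ev[ev$time_s <= start_s, , drop = FALSE]
    state <- if (nrow(prior)) prior$state[nrow(prior)] else 0
    t_on <- if (state == 1) start_s else NA_real_
    if (state == 1) {
      first_t[s] <- min(first_t[s], start_s)
      active_in_window[s] <- TRUE
    }
    inw <- ev[ev$time_s > start_s & ev$time_s < end_s, , drop = FALSE]
    for (r in seq_len(nrow(inw))) {
      if (inw$state[r] == 1 && state == 0) {
        counts[s] <- counts[s] + 1
        t_on <- inw$time_s[r]
        first_t[s] <- min(first_t[s], t_on)
        active_in_window[s] <- TRUE
        state <- 1
      } else if (inw$state[r] == 0 && state == 1) {
        durations[s] <- durations[s] + (inw$time_s[r] - t_on)
        state <- 0; t_on <- NA_real_
      }
    }
    if (state == 1 && !is.na(t_on)) durations[s] <- durations[s] + (end_s - t_on)
  }
  rank <- stats::setNames(numeric(n), ids)
  act <- which(is.finite(first_t))
  if (length(act)) rank[act] <- base::rank(first_t[act], ties.method = "first")
  edge_count <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i && graph$K[i, j] == 1 &&
          active_in_window[i] && active_in_window[j]) {
        edge_count <- edge_count + 1
      }
    }
  }
  unname(c(counts, durations, rank, edge_count))
}
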