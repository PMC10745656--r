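# Plain-text readers/writers for the pipeline's interchange formats.

#' Read an IMU stream from CSV
#'
#' Expects columns time_s, ax, ay, az, gx, gy, gz, mx, my, mz.
#' @param path CSV file path.
#' @export
read_imu_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0, "imu csv missing column(s): %s",
              paste(missing, collapse = ", "))
  df
}

#' Read ambient events from CSV (time_s, sensor_id, state)
#' @param path CSV file path.
#' @export
read_ambient_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "sensor_id", "state")
  missing <- setdiff(need, names(df))
  assert_that(length(missing) == 0, "ambient csv missing column(s): %s",
              paste(missing, collapse = ", "))
  df[order(df$time_s, df$sensor_id), , drop = FALSE]
}

#' Write / read an ambient layout as YAML
#' @param layout an [ambient_layout()]. @param path file path.
#' @export
write_layout_yaml <- function(layout, path) {
  sensors <- layout$sensors
  out <- lapply(seq_len(nrow(sensors)), function(i) {
    list(sensor_id = sensors$sensor_id[i],
         sensor_type = sensors$sensor_type[i],
         orientation = sensors$orientation[i],
         zone_lo = sensors$zone_lo[i],
         zone_hi = sensors$zone_hi[i],
         neighbors = as.list(sensors$neighbors[[i]]))
  })
  yaml::write_yaml(list(sensors = out), path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sensors <- do.call(rbind, lapply(raw$sensors, function(s) {
    data.frame(sensor_id = s$sensor_id, sensor_type = s$sensor_type,
               orientation = s$orientation, zone_lo = s$zone_lo,
               zone_hi = s$zone_hi, stringsAsFactors = FALSE)
  }))
  sensors$neighbors <- lapply(raw$sensors, function(s) unlist(s$neighbors))
  ambient_layout(sensors)
}

#' Write a segment index as CSV (modality, start_s, end_s, label)
#' @param segments list of segments. @param path file path.
#' @export
write_segment_csv <- function(segments, path) {
  df <- do.call(rbind, lapply(segments, function(s) {
    data.frame(modality = s$modality, start_s = s$start_s, end_s = s$end_s,
               label = s$label, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write per-frame skeleton points as CSV
#' @param skeletons list of skeleton_points (one per frame). @param path file.
#' @export
write_skeleton_csv <- function(skeletons, path) {
  rows <- list()
  for (j in seq_along(skeletons)) {
    sk <- skeletons[[j]]
    for (cat in names(sk$points)) {
      pts <- sk$points[[cat]]
      if (is.null(pts) || nrow(pts) == 0) next
      for (i in seq_len(nrow(pts))) {
        rows[[length(rows) + 1]] <- data.frame(
          frame_idx = j, category = cat,
          side = if (nrow(pts) == 2) c("L", "R")[i] else "C",
          row = pts[i, 1], col = pts[i, 2],
          confidence = sk$confidence[[cat]], stringsAsFactors = FALSE)
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
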