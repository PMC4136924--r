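#' Migration metrics for a single track
#'
#' Positions are converted to physical units (`pixel_size` per pixel,
#' `dt` per frame interval). `path_length` is the summed step distance,
#' `net_displacement` the start-to-end distance, `mean_speed` the path
#' length divided by the elapsed time (gap-aware: a missing frame
#' lengthens the elapsed time of the step spanning it), and
#' `directionality` the net displacement over the path length (1 for
#' straight-line motion, 0 for a closed loop). `turning_angles` are the
#' signed angles between successive steps; `rebased_endpoint` is the end
#' position translated so the track starts at the origin (rose-plot
#' coordinate).
#'
#' @param track a `Track` (see [new_track()]).
#' @param dt frame interval override; defaults to the track's own.
#' @param pixel_size pixel size override; defaults to the track's own.
#' @return object of class `TrackMetrics` (a list).
#' @export
track_metrics <- function(track, dt = NULL, pixel_size = NULL) {
  if (is.null(dt)) dt <- track$dt
  if (is.null(pixel_size)) pixel_size <- track$pixel_size
  n <- length(track$x)
  if (n < 2L) stop("track needs at least 2 positions")
  if (is.na(dt) || dt <= 0) stop("frame interval dt must be positive")
  x <- track$x * pixel_size
  y <- track$y * pixel_size
  dx <- diff(x); dy <- diff(y)
  steps <- sqrt(dx^2 + dy^2)
  path_length <- sum(steps)
  net <- sqrt((x[n] - x[1])^2 + (y[n] - y[1])^2)
  elapsed <- (track$frame[n] - track$frame[1]) * dt
  ang <- atan2(dy, dx)
  turning <- if (n > 2L) {
    d <- diff(ang)
    atan2(sin(d), cos(d))      # wrap to (-pi, pi]
  } else numeric(0)
  structure(list(track_id = track$track_id,
                 n_positions = n,
                 path_length = path_length,
                 net_displacement = net,
                 mean_speed = path_length / elapsed,
                 directionality = if (path_length > 0) net / path_length
                                  else NA_real_,
                 turning_angles = turning,
                 step_speeds = steps / (diff(track$frame) * dt),
                 rebased_endpoint = c(x = x[n] - x[1], y = y[n] - y[1]),
                 has_gaps = track$has_gaps),
            class = "TrackMetrics")
}

#' @export
print.TrackMetrics <- function(x, ...) {
  cat(sprintf(
    "<TrackMetrics '%s'> path %.2f, net %.2f, speed %.3f, directionality %.3f\n",
    x$track_id, x$path_length, x$net_displacement, x$mean_speed,
    x$directionality))
  invisible(x)
}

#' Flatten track metrics to a one-row-per-track data.frame
#' @param metrics list of `TrackMetrics`.
#' @return data.frame.
#' @export
track_metrics_table <- function(metrics) {
  do.call(rbind, lapply(metrics, function(m)
    data.frame(track_id = m$track_id, n_positions = m$n_positions,
               path_length = m$path_length,
               net_displacement = m$net_displacement,
               mean_speed = m$mean_speed,
               directionality = m$directionality,
               endpoint_x = unname(m$rebased_endpoint["x"]),
               endpoint_y = unname(m$rebased_endpoint["y"]),
               has_gaps = m$has_gaps, stringsAsFactors = FALSE)))
}

#' Per-condition summary of track metrics
#'
#' Mean and standard error of the mean for path length, mean speed and
#' directionality; the SEM of a single track is reported as `NA`.
#'
#' @param metrics non-empty list of `TrackMetrics`.
#' @return data.frame with one row per statistic (`mean`, `sem`, `n`).
#' @export
summarize_condition <- function(metrics) {
  if (!length(metrics)) stop("empty list of track metrics")
  tab <- track_metrics_table(metrics)
  sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v))
                     else NA_real_
  vars <- c("path_length", "mean_speed", "directionality")
  data.frame(metric = vars,
             mean = vapply(vars, function(v) mean(tab[[v]]), numeric(1)),
             sem = vapply(vars, function(v) sem(tab[[v]]), numeric(1)),
             n = nrow(tab), row.names = NULL, stringsAsFactors = FALSE)
}
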