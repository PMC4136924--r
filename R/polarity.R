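#' Polarity axis of a cell
#'
#' The axis is the unit vector from the region's geometric centroid
#' toward the intensity-weighted centroid of a reference channel within
#' the region. With a uropod marker such as CD44 as the reference, the
#' axis points toward the cell rear (trailing edge). Alternatives: the
#' reversed net-motion vector of a matched track (`axis_source =
#' "motion"`), or a user-supplied vector.
#'
#' @param field a `Field`.
#' @param region a `CellRegion`.
#' @param reference_channel channel name marking the rear (e.g. CD44).
#' @param min_offset minimum centroid offset in pixels below which the
#'   axis is considered undefined (default 0.5).
#' @return unit vector `c(row, col)`, or `NULL` when the reference
#'   centroid coincides with the geometric centroid (cell excluded).
#' @export
polarity_axis <- function(field, region, reference_channel,
                          min_offset = 0.5) {
  ch <- get_channel(field, reference_channel)
  w <- ch[region$pixels]
  if (sum(w) <= 0) return(NULL)
  wc <- colSums(region$pixels * w) / sum(w)
  v <- wc - region$centroid
  if (sqrt(sum(v^2)) < min_offset) return(NULL)
  v / sqrt(sum(v^2))
}

#' Polarity axis from a migration track
#'
#' The rear is opposite the direction of net motion, so the returned
#' axis is the reversed, normalized net displacement converted to
#' (row, col) components (`x` = col, `y` = row).
#'
#' @param track a `Track`.
#' @return unit vector `c(row, col)`, or `NULL` for zero net motion.
#' @export
polarity_axis_from_motion <- function(track) {
  n <- length(track$x)
  if (n < 2L) stop("track needs at least 2 positions")
  v <- c(track$y[n] - track$y[1], track$x[n] - track$x[1])
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(NULL)
  -v / nv
}

#' Fraction of marker signal in the rear half of a cell
#'
#' Splits the region by the line through the geometric centroid
#' perpendicular to `axis`; the rear half is the side the axis points
#' into. Pixels exactly on the split line contribute half their
#' intensity to each side, which makes
#' `rear_fraction(axis) + rear_fraction(-axis) = 1` exact.
#'
#' @param field a `Field`.
#' @param region a `CellRegion`.
#' @param axis unit vector `c(row, col)` pointing to the rear.
#' @param marker_channel channel whose localization is scored.
#' @return fraction in `[0, 1]`.
#' @export
rear_fraction <- function(field, region, axis, marker_channel) {
  stopifnot(length(axis) == 2L, abs(sqrt(sum(axis^2)) - 1) < 1e-6)
  ch <- get_channel(field, marker_channel)
  ints <- ch[region$pixels]
  total <- sum(ints)
  if (total <= 0) stop("zero total marker signal in region")
  proj <- sweep(region$pixels, 2, region$centroid) %*% axis
  w <- ifelse(proj > 0, 1, ifelse(proj < 0, 0, 0.5))
  sum(w * ints) / total
}

#' Classify trailing-edge marker localization for every cell of a field
#'
#' Reproduces a per-condition "fraction of cells with marker at the
#' trailing edge" readout: each cell gets a polarity axis from the
#' reference (uropod) channel, the marker channel's rear-half signal
#' fraction, and a boolean call `rear_fraction >= threshold`. Cells with
#' an undefined axis are excluded with a reason code and reported
#' separately, not counted in the summary denominator.
#'
#' @param field a `Field`.
#' @param mask label mask.
#' @param reference_channel rear (uropod) reference channel name.
#' @param marker_channel marker channel name.
#' @param threshold rear-fraction cutoff for a positive call (default 0.6).
#' @param axis_source `"reference_channel"` (default), or `"motion"` with
#'   `tracks` supplying one track per cell label.
#' @param tracks optional named list of `Track`s keyed by cell label,
#'   used when `axis_source = "motion"`.
#' @return list with `calls` (data.frame: cell_label, axis_row, axis_col,
#'   axis_source, rear_fraction, localized, flag) and `summary` (list:
#'   fraction, n_localized, n_evaluable, n_excluded).
#' @export
classify_field <- function(field, mask, reference_channel, marker_channel,
                           threshold = 0.6,
                           axis_source = c("reference_channel", "motion"),
                           tracks = NULL) {
  axis_source <- match.arg(axis_source)
  regions <- extract_regions(mask, field)
  rows <- list()
  for (reg in regions) {
    axis <- switch(axis_source,
      reference_channel = polarity_axis(field, reg, reference_channel),
      motion = {
        tr <- tracks[[as.character(reg$label)]]
        if (is.null(tr)) NULL else polarity_axis_from_motion(tr)
      })
    row <- data.frame(cell_label = reg$label, axis_row = NA_real_,
                      axis_col = NA_real_, axis_source = axis_source,
                      rear_fraction = NA_real_, localized = NA,
                      flag = "ok", stringsAsFactors = FALSE)
    if (is.null(axis)) {
      row$flag <- "undefined_axis"
    } else {
      rf <- tryCatch(rear_fraction(field, reg, axis, marker_channel),
                     error = function(e) NA_real_)
      if (is.na(rf)) {
        row$flag <- "zero_marker_signal"
      } else {
        row$axis_row <- axis[1]; row$axis_col <- axis[2]
        row$rear_fraction <- rf
        row$localized <- rf >= threshold
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  calls <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_label = integer(), axis_row = numeric(),
               axis_col = numeric(), axis_source = character(),
               rear_fraction = numeric(), localized = logical(),
               flag = character(), stringsAsFactors = FALSE)
  ev <- calls[calls$flag == "ok", , drop = FALSE]
  summary <- list(
    fraction = if (nrow(ev)) mean(ev$localized) else NA_real_,
    n_localized = sum(ev$localized),
    n_evaluable = nrow(ev),
    n_excluded = sum(calls$flag != "ok"))
  list(calls = calls, summary = summary)
}
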