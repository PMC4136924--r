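#' Mean pairwise Euclidean distance of a point set
#'
#' The average over all n(n-1)/2 unordered pairs, in the units of the
#' input coordinates. This is the distance statistic D underlying the
#' clustering index: computed on the brightest decile of a cell's pixels
#' it measures how spatially packed the strongest signal is.
#'
#' @param points n x 2 numeric matrix of coordinates.
#' @return mean pairwise distance (scalar).
#' @export
mean_pairwise_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points")
  mean(stats::dist(points))
}

#' Select the brightest decile of pixels within a cell
#'
#' Picks the `n = max(2, round(0.10 * area))` highest-intensity pixels of
#' the region (half rounds up). Ties at the cut intensity -- common with
#' integer camera counts -- are broken by distance to the region
#' centroid (nearest first), a geometric rule that moves with the image
#' under translation and right-angle rotation so the selection, and
#' hence the clustering index, stays rigid-motion invariant; any
#' remaining exact tie falls back to (row, col) order.
#'
#' @param channel intensity matrix of one channel.
#' @param region a `CellRegion` with at least 20 pixels.
#' @return n x 2 matrix of selected (row, col) coordinates.
#' @export
select_top_decile <- function(channel, region) {
  if (region$area < 20L)
    stop("region too small for top-decile selection (area < 20)")
  px <- region$pixels
  ## round half away from zero (not banker's): a 25-px region selects 3
  n <- max(2L, as.integer(floor(0.10 * region$area + 0.5)))
  ints <- channel[px]
  ctr <- colMeans(px)
  d2 <- (px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2
  ord <- order(-ints, d2, px[, 1], px[, 2])
  sel <- px[ord[seq_len(n)], , drop = FALSE]
  colnames(sel) <- c("row", "col")
  sel
}

#' Packed-square reference distance S_l
#'
#' Mean pairwise distance of `n` lattice points filling, row-major, a
#' square block of side `ceiling(sqrt(n))` at unit spacing. For n = 100
#' this is the 10 x 10 pixel square, the reference configuration for
#' maximal clustering; smaller or larger cells use the same construction
#' at their own n.
#'
#' @param n number of points (>= 2).
#' @return S_l in pixel units.
#' @export
packed_square_bound <- function(n) {
  pts <- packed_square_points(n)
  mean_pairwise_distance(pts)
}

#' Coordinates of the packed-square configuration
#' @param n number of points (>= 2).
#' @return n x 2 matrix of 1-based (row, col) lattice coordinates.
#' @export
packed_square_points <- function(n) {
  if (n < 2L) stop("need n >= 2")
  s <- ceiling(sqrt(n))
  k <- seq_len(n) - 1L
  cbind(row = k %/% s + 1L, col = k %% s + 1L)
}

## cumulative arclength of a closed digital contour: steps of length 1
## (4-neighbor) or sqrt(2) (diagonal)
.contour_arclength <- function(boundary) {
  m <- nrow(boundary)
  nxt <- rbind(boundary[-1L, , drop = FALSE], boundary[1L, , drop = FALSE])
  steps <- sqrt(rowSums((nxt - boundary)^2))
  list(steps = steps, total = sum(steps),
       cum = c(0, cumsum(steps))[seq_len(m)])
}

#' Equally spaced points along a cell's outer boundary
#'
#' Places `n` points at equal arclength intervals along the closed
#' boundary polyline (vertices at boundary pixel centers; step lengths 1
#' and sqrt(2)). Positions between vertices are linearly interpolated,
#' so placement is continuous and deterministic. The starting phase is
#' the boundary vertex farthest from the boundary centroid (first such
#' vertex in traversal order on ties): a geometric anchor that maps with
#' the region under translation and right-angle rotation, keeping the
#' scatter -- and hence S_u -- invariant under rigid motion of the image.
#'
#' @param boundary m x 2 ordered closed contour (from [moore_contour()]).
#' @param n number of points.
#' @return n x 2 matrix of (row, col) coordinates.
#' @export
perimeter_scatter_points <- function(boundary, n) {
  m <- nrow(boundary)
  if (m < n) stop("boundary (", m, " steps) shorter than n = ", n)
  ## canonical, rotation-equivariant starting phase
  ctr <- colMeans(boundary)
  d2 <- (boundary[, 1] - ctr[1])^2 + (boundary[, 2] - ctr[2])^2
  i0 <- which.max(d2)
  if (i0 > 1L)
    boundary <- rbind(boundary[i0:m, , drop = FALSE],
                      boundary[seq_len(i0 - 1L), , drop = FALSE])
  arc <- .contour_arclength(boundary)
  targets <- (seq_len(n) - 1L) * arc$total / n
  ## vertex arclengths arc$cum[i] for i = 1..m; closing edge returns to 1
  idx <- findInterval(targets, arc$cum)
  p1 <- boundary[idx, , drop = FALSE]
  i2 <- ifelse(idx == m, 1L, idx + 1L)
  p2 <- boundary[i2, , drop = FALSE]
  frac <- (targets - arc$cum[idx]) / arc$steps[idx]
  out <- p1 + frac * (p2 - p1)
  colnames(out) <- c("row", "col")
  out
}

#' Perimeter-scatter reference distance S_u
#'
#' Mean pairwise distance of `n` points uniformly scattered (at equal
#' arclength spacing) along the region's outer boundary -- the reference
#' configuration for a fully unclustered, membrane-uniform signal.
#' Placement is deterministic, so S_u is a fixed per-cell bound rather
#' than a Monte-Carlo estimate.
#'
#' @param region a `CellRegion` with a traced boundary.
#' @param n number of points (>= 2, at most the boundary length).
#' @return S_u in pixel units.
#' @export
perimeter_scatter_bound <- function(region, n) {
  if (n < 2L) stop("need n >= 2")
  mean_pairwise_distance(perimeter_scatter_points(region$boundary, n))
}

#' Per-cell receptor clustering index
#'
#' For one cell and channel: selects the brightest-decile pixel set,
#' computes its mean pairwise distance `d_alpha`, the packed-square
#' reference `s_l` (maximal clustering) and the perimeter-scatter
#' reference `s_u` (no clustering), and normalizes
#' \deqn{ci = (S_u - D\alpha) / (S_u - S_l).}
#' `ci` is ~1 for a tightly packed cap and ~0 for signal spread uniformly
#' around the membrane. The value is not clipped: configurations more
#' dispersed than the perimeter scatter (ci < 0) or more compact than the
#' packed square on a non-lattice geometry (ci > 1) are possible and are
#' flagged rather than hidden.
#'
#' @param channel intensity matrix of the scored channel.
#' @param region a `CellRegion`.
#' @return object of class `ClusteringResult`: list with `cell_label`,
#'   `n`, `selected_pixels`, `d_alpha`, `s_l`, `s_u`, `ci`, `flag`.
#' @export
clustering_index <- function(channel, region) {
  sel <- select_top_decile(channel, region)
  n <- nrow(sel)
  d_alpha <- mean_pairwise_distance(sel)
  s_l <- packed_square_bound(n)
  s_u <- perimeter_scatter_bound(region, n)
  if (s_u <= s_l)
    stop("degenerate region: perimeter bound not above packed bound")
  ci <- (s_u - d_alpha) / (s_u - s_l)
  structure(list(cell_label = region$label, n = n, selected_pixels = sel,
                 d_alpha = d_alpha, s_l = s_l, s_u = s_u, ci = ci,
                 flag = if (ci < 0 || ci > 1) "out_of_range" else "ok"),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf(
    "<ClusteringResult cell %d> n = %d, Da = %.3f, Sl = %.3f, Su = %.3f, ci = %.4f (%s)\n",
    x$cell_label, x$n, x$d_alpha, x$s_l, x$s_u, x$ci, x$flag))
  invisible(x)
}

#' Score clustering for every cell and channel of a field
#'
#' Cells whose preconditions fail (too small for the top-decile rule, or
#' a boundary shorter than n) are kept in the output with a reason code
#' in `flag` and `NA` statistics, never silently dropped.
#'
#' @param field a `Field`.
#' @param mask label mask aligned with `field`.
#' @param channels channel names to score (default: all).
#' @return data.frame with columns `field_id, cell_label, channel, n,
#'   d_alpha, s_l, s_u, ci, flag`.
#' @export
score_field <- function(field, mask, channels = channel_names(field)) {
  missing_ch <- setdiff(channels, channel_names(field))
  if (length(missing_ch))
    stop("channel(s) absent: ", paste(missing_ch, collapse = ", "))
  regions <- extract_regions(mask, field)
  rows <- list()
  for (reg in regions) {
    for (ch in channels) {
      row <- data.frame(field_id = field$field_id, cell_label = reg$label,
                        channel = ch, n = NA_integer_, d_alpha = NA_real_,
                        s_l = NA_real_, s_u = NA_real_, ci = NA_real_,
                        flag = NA_character_, stringsAsFactors = FALSE)
      if (reg$area < 20L) {
        row$flag <- "too_small"
      } else {
        res <- tryCatch(clustering_index(get_channel(field, ch), reg),
                        error = function(e) conditionMessage(e))
        if (is.character(res)) {
          row$flag <- if (grepl("shorter than", res)) "short_boundary"
                      else "error"
        } else {
          row$n <- res$n; row$d_alpha <- res$d_alpha
          row$s_l <- res$s_l; row$s_u <- res$s_u; row$ci <- res$ci
          row$flag <- res$flag
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows))
    return(data.frame(field_id = character(), cell_label = integer(),
                      channel = character(), n = integer(),
                      d_alpha = numeric(), s_l = numeric(), s_u = numeric(),
                      ci = numeric(), flag = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
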