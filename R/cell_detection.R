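#' Detection parameters for cell segmentation
#'
#' Defaults reflect lymphocytes imaged at roughly 0.3--0.7 um/px: a cell
#' of ~10 um diameter covers a few hundred to a few thousand pixels. The
#' solidity filter rejects fused cell clumps instead of splitting them,
#' so only singly detected cells enter downstream statistics.
#'
#' @param detection_channel channel name, or `"sum"` to detect on the
#'   pixel-wise sum of all channels (robust when a cell is dim in one
#'   stain because its signal is capped elsewhere).
#' @param min_area,max_area component area bounds in pixels.
#' @param min_solidity minimum area / convex-hull-area ratio in (0, 1].
#' @param exclude_border drop components touching the image border.
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @return list of class `DetectionParams`.
#' @export
detection_params <- function(detection_channel = "sum",
                             min_area = 200, max_area = 10000,
                             min_solidity = 0.7,
                             exclude_border = TRUE,
                             smoothing_sigma = 1.0) {
  stopifnot(min_area > 0, min_area < max_area,
            min_solidity > 0, min_solidity <= 1, smoothing_sigma >= 0)
  structure(list(detection_channel = detection_channel,
                 min_area = min_area, max_area = max_area,
                 min_solidity = min_solidity,
                 exclude_border = exclude_border,
                 smoothing_sigma = smoothing_sigma),
            class = "DetectionParams")
}

#' 8-connected component labeling of a binary matrix
#'
#' Flood fill on a zero-padded copy so neighbor arithmetic never wraps
#' across image edges. Labels are assigned in column-major scan order of
#' each component's first pixel, so the result is deterministic.
#'
#' @param bin logical or 0/1 matrix.
#' @return integer matrix of labels, 0 = background.
#' @export
label_components <- function(bin) {
  bin <- as.matrix(bin) != 0
  nr <- nrow(bin); nc <- ncol(bin)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- bin
  npr <- nr + 2L
  off <- c(-1L, 1L, -npr, npr, -npr - 1L, -npr + 1L, npr - 1L, npr + 1L)
  lab <- matrix(0L, npr, nc + 2L)
  todo <- which(pad)
  k <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    k <- k + 1L
    lab[s] <- k
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, off, `+`)))
      nb <- nb[pad[nb] & lab[nb] == 0L]
      lab[nb] <- k
      frontier <- nb
    }
  }
  lab[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
}

## solidity = area / number of pixels whose centers fall in the convex
## hull of the region's pixel corners (pixels treated as unit squares,
## so a filled rectangle has solidity 1)
.region_solidity <- function(px) {
  if (nrow(px) <= 2L) return(1)
  corners <- rbind(cbind(px[, 1] - 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] - 0.5, px[, 2] + 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] - 0.5),
                   cbind(px[, 1] + 0.5, px[, 2] + 0.5))
  h <- grDevices::chull(corners)
  hull <- corners[h, , drop = FALSE]
  rr <- seq(min(px[, 1]), max(px[, 1]))
  cc <- seq(min(px[, 2]), max(px[, 2]))
  grid <- cbind(rep(rr, times = length(cc)), rep(cc, each = length(rr)))
  inside <- pracma::inpolygon(grid[, 1], grid[, 2],
                              hull[, 1], hull[, 2], boundary = TRUE)
  nrow(px) / sum(inside)
}

#' Segment single cells in a fluorescence field
#'
#' Pipeline: Gaussian smoothing of the detection channel, global Otsu
#' threshold, hole filling, 8-connected component labeling, then filters
#' on area, solidity and border contact. Clumps of touching cells fail
#' the solidity filter and are rejected rather than split, mirroring an
#' analysis restricted to singly detected cells.
#'
#' @param field a `Field`.
#' @param params a [detection_params()] object.
#' @return integer label mask (relabeled to `{1..K}`); an empty mask with
#'   a warning when no component survives the filters.
#' @export
segment_field <- function(field, params = detection_params()) {
  img <- get_channel(field, params$detection_channel)
  if (diff(range(img)) == 0)
    stop("constant detection image: no threshold definable")
  sm <- img
  if (params$smoothing_sigma > 0)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                   sigma = params$smoothing_sigma))
  ## Otsu on log-compressed intensity: fluorescence foreground spans
  ## orders of magnitude (dim cytoplasm vs bright membrane cap), which
  ## breaks Otsu's bimodal assumption on the raw scale; log1p restores a
  ## background-vs-cell histogram and the threshold stays global.
  ## The threshold LEVEL comes from the smoothed histogram (noise
  ## robustness) but is APPLIED to the unsmoothed image: a bright
  ## membrane rim otherwise drags the smoothed level set ~1.5 px outside
  ## the true cell edge
  lg_sm <- log1p(pmax(sm, 0))
  rng <- range(lg_sm)
  thr <- EBImage::otsu(EBImage::Image((lg_sm - rng[1]) / diff(rng)),
                       range = c(0, 1), levels = 256)
  bin <- (log1p(pmax(img, 0)) - rng[1]) / diff(rng) > thr
  bin <- as.matrix(EBImage::fillHull(EBImage::Image(bin))) > 0
  lab <- label_components(bin)
  nlab <- max(lab)
  if (nlab == 0L) {
    warning("no components above threshold")
    return(lab)
  }
  keep <- logical(nlab)
  nr <- nrow(lab); nc <- ncol(lab)
  counts <- tabulate(lab[lab > 0L], nbins = nlab)
  for (k in seq_len(nlab)) {
    if (counts[k] < params$min_area || counts[k] > params$max_area) next
    px <- which(lab == k, arr.ind = TRUE)
    if (params$exclude_border &&
        (any(px[, 1] %in% c(1L, nr)) || any(px[, 2] %in% c(1L, nc)))) next
    if (.region_solidity(px) < params$min_solidity) next
    keep[k] <- TRUE
  }
  lab[lab > 0L & !keep[pmax(lab, 1L)]] <- 0L
  if (all(lab == 0L)) warning("no components survived the filters")
  relabel_mask(lab)
}

#' Moore-neighbor boundary tracing
#'
#' Traces the outer boundary of an 8-connected pixel region, starting at
#' the topmost-then-leftmost region pixel and proceeding clockwise in
#' image coordinates (row down, col right). One-pixel-wide arms are
#' traversed in both directions, as a closed contour must.
#'
#' @param px n x 2 matrix of (row, col) pixel coordinates (8-connected).
#' @return m x 2 matrix of ordered boundary pixel coordinates forming a
#'   closed contour (last vertex connects back to the first).
#' @export
moore_contour <- function(px) {
  if (nrow(px) < 3L) stop("cannot trace a contour of fewer than 3 pixels")
  rmin <- min(px[, 1]); cmin <- min(px[, 2])
  nr <- max(px[, 1]) - rmin + 3L
  nc <- max(px[, 2]) - cmin + 3L
  m <- matrix(FALSE, nr, nc)
  m[cbind(px[, 1] - rmin + 2L, px[, 2] - cmin + 2L)] <- TRUE
  ## clockwise neighbor ring starting at N (image coords: row down, col right)
  dirs <- rbind(c(-1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L),
                c(1L, 0L), c(1L, -1L), c(0L, -1L), c(-1L, -1L))
  dir_index <- function(dp)
    which(dirs[, 1] == dp[1] & dirs[, 2] == dp[2])
  start_r <- min(px[, 1]) - rmin + 2L
  start_c <- min(px[px[, 1] - rmin + 2L == start_r, 2]) - cmin + 2L
  s <- c(start_r, start_c)
  b <- s + c(-1L, 0L)      # start is topmost, so the pixel above is background
  p <- s
  cap <- nrow(px) * 8L + 8L
  contour <- matrix(0L, cap, 2L)
  contour[1L, ] <- p
  len <- 1L
  ## terminate when a (pixel, backtrack-direction) state repeats: the
  ## trace is then exactly one period of the boundary cycle
  codes <- integer(cap)
  n_codes <- 0L
  first_idx <- NA_integer_
  repeat {
    d0 <- dir_index(b - p)
    prev <- b
    advanced <- FALSE
    for (j in 1:7) {
      idx <- ((d0 - 1L + j) %% 8L) + 1L
      q <- p + dirs[idx, ]
      if (m[q[1], q[2]]) {
        b <- prev
        p <- q
        advanced <- TRUE
        break
      }
      prev <- q
    }
    if (!advanced) break                       # isolated pixel; n >= 3 rules it out
    code <- ((p[1] * nc + p[2]) * 8L + dir_index(b - p))
    hit <- match(code, codes[seq_len(n_codes)])
    if (!is.na(hit)) { first_idx <- hit + 1L; break }
    len <- len + 1L
    if (len > cap) stop("contour tracing did not terminate")
    contour[len, ] <- p
    n_codes <- n_codes + 1L
    codes[n_codes] <- code
  }
  ## drop any transient prefix before the cycle, and the duplicated
  ## closing vertex (the cycle normally closes through the start pixel)
  lo <- if (!is.na(first_idx) && first_idx > 2L) first_idx - 1L else 1L
  ctr <- contour[lo:len, , drop = FALSE]
  if (nrow(ctr) > 1L && all(ctr[nrow(ctr), ] == ctr[1L, ]))
    ctr <- ctr[-nrow(ctr), , drop = FALSE]
  ctr[, 1] <- ctr[, 1] + rmin - 2L
  ctr[, 2] <- ctr[, 2] + cmin - 2L
  colnames(ctr) <- c("row", "col")
  ctr
}

## second central moments with the unit-square pixel correction (1/12 per
## axis) so one-pixel-wide regions get a finite minor axis
.ellipse_axes <- function(px) {
  mu <- colMeans(px)
  d <- sweep(px, 2, mu)
  n <- nrow(px)
  mrr <- sum(d[, 1]^2) / n + 1 / 12
  mcc <- sum(d[, 2]^2) / n + 1 / 12
  mrc <- sum(d[, 1] * d[, 2]) / n
  tr <- mrr + mcc
  det_ <- mrr * mcc - mrc^2
  disc <- sqrt(max(tr^2 / 4 - det_, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  c(major = 4 * sqrt(l1), minor = 4 * sqrt(max(l2, 0)))
}

#' Extract per-cell regions from a label mask
#'
#' Computes, for every label, the pixel set, outer boundary contour
#' (Moore tracing, clockwise, canonical start), centroid, area, best-fit
#' ellipse axes from second central moments, elongation, solidity and
#' border contact. Labels with fewer than 3 pixels cannot be traced and
#' are skipped with a warning.
#'
#' @param mask integer label mask.
#' @param field optional `Field` the mask belongs to (checked for shape).
#' @return list of `CellRegion` objects.
#' @export
extract_regions <- function(mask, field = NULL) {
  mask <- as.matrix(mask)
  if (!is.null(field) && !identical(dim(mask), dim(field)))
    stop("mask and field dimensions differ")
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  nr <- nrow(mask); nc <- ncol(mask)
  out <- list()
  for (k in labs) {
    px <- which(mask == k, arr.ind = TRUE)
    colnames(px) <- c("row", "col")
    if (nrow(px) < 3L) {
      warning("label ", k, " has fewer than 3 pixels; skipped")
      next
    }
    boundary <- moore_contour(px)
    axes <- .ellipse_axes(px)
    out[[length(out) + 1L]] <- structure(list(
      label = as.integer(k),
      pixels = px,
      boundary = boundary,
      centroid = colMeans(px),
      area = nrow(px),
      major_axis = unname(axes["major"]),
      minor_axis = unname(axes["minor"]),
      elongation = unname(axes["major"] / max(axes["minor"], 1e-12)),
      solidity = .region_solidity(px),
      touches_border = any(px[, 1] %in% c(1L, nr)) ||
        any(px[, 2] %in% c(1L, nc))),
      class = "CellRegion")
  }
  out
}

#' @export
print.CellRegion <- function(x, ...) {
  cat(sprintf(
    "<CellRegion %d> area %d px, centroid (%.1f, %.1f), elongation %.2f\n",
    x$label, x$area, x$centroid[1], x$centroid[2], x$elongation))
  invisible(x)
}
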