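#' Channel parameters for a synthetic cell
#'
#' The membrane signal of a synthetic cell is concentrated on an
#' elliptical annulus with angular density proportional to
#' `exp(kappa * cos(theta - mu))` -- a von Mises cap. `kappa = 0` gives a
#' uniform membrane ring (unpolarized stain); large `kappa` gives a
#' tight cap (polarized stain). The density is normalized by the Bessel
#' factor `I0(kappa)` so the total membrane signal is approximately
#' independent of `kappa`. The cap direction `mu` is expressed per cell
#' as `polarity_direction + cap_offset`, so a marker can be placed at
#' the cell rear (`cap_offset = 0`) or front (`cap_offset = pi`)
#' relative to the reference stain.
#'
#' Membrane receptors are not a smooth film: they sit in microclusters,
#' so the rendered membrane term carries multiplicative gamma speckle
#' (`speckle_shape` = gamma shape; mean 1, CV `1/sqrt(shape)`;
#' `Inf` disables it). This granularity matters: a noiseless smooth
#' profile has the same intensity *ranking* for every `kappa > 0`, which
#' would make any rank-based clustering statistic blind to the cap
#' concentration.
#'
#' @param kappa von Mises angular concentration (>= 0).
#' @param cap_offset angular offset of the cap from the cell's polarity
#'   direction, radians.
#' @param membrane_amplitude peak-scale membrane intensity (camera counts).
#' @param cytoplasm_level uniform interior intensity (camera counts).
#' @param speckle_shape gamma shape of the membrane microcluster speckle
#'   (default 3; `Inf` = smooth membrane).
#' @return list of class `ChannelSpec`.
#' @export
membrane_channel <- function(kappa = 0, cap_offset = 0,
                             membrane_amplitude = 100,
                             cytoplasm_level = 20,
                             speckle_shape = 3) {
  stopifnot(kappa >= 0, membrane_amplitude >= 0, cytoplasm_level >= 0,
            speckle_shape > 0)
  structure(list(kappa = kappa, cap_offset = cap_offset,
                 membrane_amplitude = membrane_amplitude,
                 cytoplasm_level = cytoplasm_level,
                 speckle_shape = speckle_shape),
            class = "ChannelSpec")
}

#' Geometry and staining of one synthetic cell
#'
#' Cells are ellipses with a membrane annulus of the given width. Angles
#' follow the image convention used throughout the package: `theta =
#' atan2(drow, dcol)`, so `mu = 0` points toward +col (right) and
#' `mu = pi/2` toward +row (down).
#'
#' @param center `(row, col)` of the cell center.
#' @param semi_axes `(a, b)` ellipse semi-axes in pixels (both >= 5).
#' @param orientation angle of the `a` axis, radians.
#' @param membrane_width radial width of the membrane annulus, pixels.
#' @param polarity_direction direction of the cell rear, radians.
#' @param channels named list of [membrane_channel()] specs.
#' @return list of class `SyntheticCellSpec`.
#' @export
synthetic_cell_spec <- function(center, semi_axes, orientation = 0,
                                membrane_width = 3,
                                polarity_direction = 0,
                                channels = list(cd44 = membrane_channel())) {
  stopifnot(length(center) == 2L, length(semi_axes) == 2L,
            all(semi_axes >= 5), membrane_width >= 1,
            length(channels) >= 1L, !is.null(names(channels)))
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = orientation,
                 membrane_width = membrane_width,
                 polarity_direction = polarity_direction,
                 channels = channels),
            class = "SyntheticCellSpec")
}

#' Specification of a synthetic multi-cell field
#'
#' @param size `(rows, cols)` of the image.
#' @param cells list of [synthetic_cell_spec()]s; cells must not overlap.
#' @param background_level uniform background intensity (camera counts).
#' @param read_noise_sd additive Gaussian read noise sd (camera counts).
#' @param shot_noise apply Poisson shot noise to the expected intensity.
#' @param seed mandatory RNG seed for the noise draw.
#' @param field_id identifier.
#' @return list of class `SyntheticFieldSpec`.
#' @export
synthetic_field_spec <- function(size, cells, background_level = 5,
                                 read_noise_sd = 2, shot_noise = TRUE,
                                 seed, field_id = "synthetic") {
  if (missing(seed)) stop("a seed is mandatory")
  structure(list(size = as.integer(size), cells = cells,
                 background_level = background_level,
                 read_noise_sd = read_noise_sd, shot_noise = shot_noise,
                 seed = as.integer(seed), field_id = field_id),
            class = "SyntheticFieldSpec")
}

## expected (noise-free) intensity of one cell within its bounding box;
## returns list(rows, cols, inside, per-channel intensity contributions)
.cell_expected <- function(cell, size) {
  a <- cell$semi_axes[1]; b <- cell$semi_axes[2]
  rmax <- max(a, b) + 2
  rows <- max(1L, floor(cell$center[1] - rmax)):min(size[1], ceiling(cell$center[1] + rmax))
  cols <- max(1L, floor(cell$center[2] - rmax)):min(size[2], ceiling(cell$center[2] + rmax))
  dr <- outer(rows - cell$center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cell$center[2])
  phi <- cell$orientation
  u <- dc * cos(phi) + dr * sin(phi)
  v <- -dc * sin(phi) + dr * cos(phi)
  q <- sqrt((u / a)^2 + (v / b)^2)
  inside <- q <= 1
  band <- 1 - cell$membrane_width / mean(c(a, b))
  membrane <- inside & q >= band
  theta <- atan2(dr, dc)
  ch_int <- lapply(cell$channels, function(cs) {
    mu <- cell$polarity_direction + cs$cap_offset
    cap <- exp(cs$kappa * cos(theta - mu)) / besselI(cs$kappa, 0)
    list(cyto = cs$cytoplasm_level * inside,
         membrane = cs$membrane_amplitude * cap * membrane,
         speckle_shape = cs$speckle_shape)
  })
  list(rows = rows, cols = cols, inside = inside, channels = ch_int)
}

## deterministic core renderer; consumes the current RNG stream
.render <- function(spec) {
  size <- spec$size
  ch_names <- names(spec$cells[[1]]$channels)
  expected <- stats::setNames(
    lapply(ch_names, function(x) matrix(spec$background_level,
                                        size[1], size[2])), ch_names)
  mask <- matrix(0L, size[1], size[2])
  truth <- list()
  for (i in seq_along(spec$cells)) {
    cell <- spec$cells[[i]]
    if (!identical(sort(names(cell$channels)), sort(ch_names)))
      stop("all cells must share the same channel names")
    ce <- .cell_expected(cell, size)
    for (nm in ch_names) {
      term <- ce$channels[[nm]]
      memb <- term$membrane
      if (is.finite(term$speckle_shape)) {
        on_mem <- memb > 0
        memb[on_mem] <- memb[on_mem] *
          stats::rgamma(sum(on_mem), shape = term$speckle_shape,
                        rate = term$speckle_shape)
      }
      expected[[nm]][ce$rows, ce$cols] <-
        expected[[nm]][ce$rows, ce$cols] + term$cyto + memb
    }
    sub <- mask[ce$rows, ce$cols]
    if (any(sub[ce$inside] != 0L)) stop("cells overlap; invalid placement")
    sub[ce$inside] <- i
    mask[ce$rows, ce$cols] <- sub
    for (nm in ch_names) {
      cs <- cell$channels[[nm]]
      truth[[length(truth) + 1L]] <- data.frame(
        label = i, channel = nm,
        center_row = cell$center[1], center_col = cell$center[2],
        a = cell$semi_axes[1], b = cell$semi_axes[2],
        orientation = cell$orientation,
        polarity_direction = cell$polarity_direction,
        kappa = cs$kappa,
        mu = cell$polarity_direction + cs$cap_offset,
        stringsAsFactors = FALSE)
    }
  }
  channels <- lapply(expected, function(ex) {
    img <- if (spec$shot_noise)
      matrix(stats::rpois(length(ex), lambda = ex), nrow(ex), ncol(ex))
    else ex
    if (spec$read_noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(ex), sd = spec$read_noise_sd),
                          nrow(ex), ncol(ex))
    pmin(pmax(round(img), 0), 65535)
  })
  list(field = new_field(channels, field_id = spec$field_id),
       mask = mask,
       truth = do.call(rbind, truth))
}

#' Render a synthetic micrograph with ground truth
#'
#' Builds the expected intensity image (background + cytoplasmic disk +
#' von Mises membrane cap per channel, with multiplicative microcluster
#' speckle on the membrane term), applies the camera noise model
#' (Poisson shot noise on the expected counts plus additive Gaussian
#' read noise, rounded to integer counts and clamped at zero), and
#' returns the field together with its ground-truth label mask and a
#' per-cell, per-channel truth table.
#'
#' @param spec a [synthetic_field_spec()].
#' @return list with `field` (a `Field`), `mask` (integer matrix) and
#'   `truth` (data.frame: label, channel, center, axes, orientation,
#'   polarity direction, kappa, mu).
#' @export
render_field <- function(spec) {
  set.seed(spec$seed)
  .render(spec)
}

## rejection-sample non-overlapping cell centers; bounding-circle test
## guarantees >= min_gap background between any two cells
.sample_centers <- function(n, size, radii, min_gap, margin,
                            max_attempts = 1000L) {
  centers <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      cand <- c(stats::runif(1, margin[i] + 1, size[1] - margin[i]),
                stats::runif(1, margin[i] + 1, size[2] - margin[i]))
      ok <- TRUE
      if (i > 1L) {
        d <- sqrt(rowSums((centers[seq_len(i - 1L), , drop = FALSE] -
                           matrix(cand, i - 1L, 2, byrow = TRUE))^2))
        ok <- all(d >= radii[seq_len(i - 1L)] + radii[i] + min_gap)
      }
      if (ok) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("could not place ", n, " cells: field too crowded")
  }
  centers
}

#' Simulate a field of randomly placed polarized cells
#'
#' Samples cell geometry (semi-axes, orientation, polarity direction)
#' and placement (rejection sampling with a minimum background gap
#' between cells), then renders with [render_field()]'s camera model.
#' All randomness flows from the single `seed`.
#'
#' @param n_cells number of cells.
#' @param size `(rows, cols)` image size.
#' @param channels named list of [membrane_channel()] specs shared by all
#'   cells (each cell gets its own random polarity direction).
#' @param seed RNG seed.
#' @param a_range,b_range uniform sampling ranges for the semi-axes (px).
#' @param membrane_width membrane annulus width (px).
#' @param min_gap minimum background gap between cells (px).
#' @param background_level,read_noise_sd,shot_noise camera model, as in
#'   [synthetic_field_spec()].
#' @param field_id identifier.
#' @return as [render_field()]: list(field, mask, truth).
#' @export
simulate_field <- function(n_cells, size = c(300, 300),
                           channels = list(cd44 = membrane_channel(kappa = 4)),
                           seed = 1,
                           a_range = c(10, 16), b_range = c(8, 12),
                           membrane_width = 3, min_gap = 8,
                           background_level = 5, read_noise_sd = 2,
                           shot_noise = TRUE, field_id = "simulated") {
  set.seed(seed)
  a <- stats::runif(n_cells, a_range[1], a_range[2])
  b <- stats::runif(n_cells, b_range[1], b_range[2])
  orient <- stats::runif(n_cells, 0, 2 * pi)
  poldir <- stats::runif(n_cells, 0, 2 * pi)
  radii <- pmax(a, b)
  centers <- .sample_centers(n_cells, size, radii, min_gap,
                             margin = radii + 2)
  cells <- lapply(seq_len(n_cells), function(i)
    synthetic_cell_spec(center = centers[i, ], semi_axes = c(a[i], b[i]),
                        orientation = orient[i],
                        membrane_width = membrane_width,
                        polarity_direction = poldir[i],
                        channels = channels))
  spec <- synthetic_field_spec(size = size, cells = cells,
                               background_level = background_level,
                               read_noise_sd = read_noise_sd,
                               shot_noise = shot_noise, seed = seed,
                               field_id = field_id)
  ## seed already consumed above; render on the continuing stream
  .render(spec)
}

#' Generate persistent-random-walk migration tracks
#'
#' Headings evolve by wrapped-normal turns whose standard deviation is
#' `sqrt(-2 * log(persistence))`, so `persistence` is the expected
#' per-step heading correlation: 1 gives straight-line motion, 0 gives
#' uncorrelated (uniform) turning. Step lengths are lognormal with mean
#' `speed * dt` (jitter `sdlog` on the log scale), so the long-run mean
#' speed equals `speed`.
#'
#' @param n number of tracks.
#' @param speed mean speed (length units per time unit).
#' @param persistence per-step heading correlation in `[0, 1)`.
#' @param n_frames positions per track.
#' @param dt frame interval (time units).
#' @param seed RNG seed.
#' @param sdlog lognormal step-length jitter (log scale).
#' @param start_box `(rows, cols)` box for uniform start positions.
#' @param pixel_size physical length per pixel for the emitted
#'   coordinates (positions are stored in pixels).
#' @return list of `Track` objects.
#' @export
generate_tracks <- function(n, speed, persistence, n_frames, dt, seed,
                            sdlog = 0.2, start_box = c(500, 500),
                            pixel_size = 1.0) {
  stopifnot(persistence >= 0, persistence < 1, speed > 0, dt > 0,
            n_frames >= 2)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    heading <- stats::runif(1, 0, 2 * pi)
    pos <- matrix(NA_real_, n_frames, 2)
    pos[1, ] <- c(stats::runif(1, 0, start_box[2]),
                  stats::runif(1, 0, start_box[1]))
    step_len <- stats::rlnorm(n_frames - 1,
                              meanlog = log(speed * dt) - sdlog^2 / 2,
                              sdlog = sdlog) / pixel_size
    turns <- if (persistence == 0)
      stats::runif(n_frames - 1, -pi, pi)
    else
      stats::rnorm(n_frames - 1, sd = sqrt(-2 * log(persistence)))
    for (t in seq_len(n_frames - 1)) {
      heading <- heading + turns[t]
      pos[t + 1, ] <- pos[t, ] + step_len[t] * c(cos(heading), sin(heading))
    }
    new_track(sprintf("track_%03d", i), frame = seq_len(n_frames) - 1L,
              x = pos[, 1], y = pos[, 2], dt = dt,
              pixel_size = pixel_size)
  })
}

#' Write a ground-truthed benchmark dataset to disk
#'
#' For each named condition, renders `n_fields` synthetic fields and
#' writes the images (multi-channel TIFF), ground-truth masks, truth
#' tables (CSV) and persistent-random-walk tracks (CSV), plus a
#' `config.yaml` directly consumable by [run_pipeline()]. Re-running
#' with the same seed reproduces every file.
#'
#' @param condition_specs named list; each element is a list with
#'   `channels` (named list of [membrane_channel()]), optional
#'   `n_fields`, `cells_per_field`, `size`, and optional `tracks`
#'   (list: speed, persistence, n, n_frames, dt).
#' @param out_dir output directory (created).
#' @param seed master seed; per-field seeds are derived from it.
#' @return `out_dir`, invisibly.
#' @export
make_benchmark <- function(condition_specs, out_dir, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_conditions <- list()
  for (ci in seq_along(condition_specs)) {
    cname <- names(condition_specs)[ci]
    cs <- condition_specs[[ci]]
    n_fields <- cs$n_fields %||% 5L
    n_cells <- cs$cells_per_field %||% 10L
    size <- cs$size %||% c(300L, 300L)
    cdir <- file.path(out_dir, cname)
    dir.create(cdir, showWarnings = FALSE)
    truth_all <- list()
    field_files <- character(0)
    ch_names <- names(cs$channels)
    for (fi in seq_len(n_fields)) {
      fseed <- (seed * 1000L + ci * 100L + fi) %% .Machine$integer.max
      sim <- simulate_field(n_cells, size = size, channels = cs$channels,
                            seed = fseed,
                            field_id = sprintf("%s_f%02d", cname, fi))
      fpath <- file.path(cdir, sprintf("field_%02d.tif", fi))
      write_field(sim$field, fpath)
      write_mask(sim$mask, file.path(cdir, sprintf("mask_%02d.tif", fi)))
      sim$truth$field_id <- sim$field$field_id
      truth_all[[fi]] <- sim$truth
      field_files <- c(field_files, basename(fpath))
    }
    utils::write.csv(do.call(rbind, truth_all),
                     file.path(cdir, "truth.csv"), row.names = FALSE)
    if (!is.null(cs$tracks)) {
      tr <- generate_tracks(cs$tracks$n %||% 50L,
                            speed = cs$tracks$speed %||% 5,
                            persistence = cs$tracks$persistence %||% 0.7,
                            n_frames = cs$tracks$n_frames %||% 30L,
                            dt = cs$tracks$dt %||% 10,
                            seed = (seed * 1000L + ci) %% .Machine$integer.max)
      write_tracks(tr, file.path(cdir, "tracks.csv"))
    }
    cfg_conditions[[cname]] <- list(
      fields = file.path(cname, field_files),
      channels = ch_names,
      tracks = if (!is.null(cs$tracks)) file.path(cname, "tracks.csv"))
  }
  yaml::write_yaml(list(seed = seed, conditions = cfg_conditions),
                   file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
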