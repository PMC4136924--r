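#' Construct a multi-channel fluorescence field
#'
#' A `Field` holds one or more co-registered 2D intensity channels of a
#' single imaged position, together with the physical pixel size. All
#' channels must share dimensions; intensities must be finite and
#' non-negative. Intensities are stored exactly as supplied -- never
#' rescaled -- because downstream statistics mix rank-based selection
#' (top-decile pixels) with absolute thresholds.
#'
#' Matrices use R's native 1-based `(row, col)` indexing. The only place
#' an `(x, y)` convention appears is the track CSV boundary, where
#' `x = col`, `y = row` (see [read_tracks()]).
#'
#' @param channels named list of numeric matrices, all the same size.
#' @param pixel_size physical length per pixel (arbitrary units, default 1).
#' @param field_id identifier string.
#' @return An object of class `Field`.
#' @export
new_field <- function(channels, pixel_size = 1.0, field_id = "field") {
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty named list of matrices")
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop("every channel must be named")
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      any(vapply(dims, length, integer(1)) != 2L))
    stop("channels must be 2D matrices")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all channels must share dimensions")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(is.finite(ch)))
      stop("channel '", nm, "' contains non-finite values")
    if (any(ch < 0))
      stop("channel '", nm, "' contains negative intensities")
    storage.mode(channels[[nm]]) <- "double"
  }
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  structure(list(channels = channels, pixel_size = as.numeric(pixel_size),
                 field_id = as.character(field_id)),
            class = "Field")
}

#' @export
print.Field <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<Field '%s'> %d x %d px, pixel_size = %g\n  channels: %s\n",
              x$field_id, d[1], d[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
dim.Field <- function(x) dim(x$channels[[1]])

#' Names of the channels in a Field
#' @param field a [new_field()] object.
#' @return character vector of channel names.
#' @export
channel_names <- function(field) names(field$channels)

#' Fetch one channel of a Field
#'
#' `"sum"` returns the pixel-wise sum of all channels, which is useful as
#' a detection image when cells may be dim in any single stain.
#'
#' @param field a `Field`.
#' @param channel channel name, or `"sum"`.
#' @return numeric matrix.
#' @export
get_channel <- function(field, channel) {
  if (identical(channel, "sum"))
    return(Reduce(`+`, field$channels))
  if (!channel %in% names(field$channels))
    stop("channel '", channel, "' not present; available: ",
         paste(names(field$channels), collapse = ", "))
  field$channels[[channel]]
}

## tiff stores pixels in [0,1]; integer data up to 16 bits round-trips
## exactly through a 1/65535 scaling. r-png can only write 8-bit files,
## so the PNG path is limited to values up to 255.
.MAXU16 <- 65535
.MAXU8 <- 255

.read_pages <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!file.exists(path)) stop("file not found: ", path)
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  } else if (ext == "png") {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) {
      pages <- lapply(seq_len(dim(img)[3]), function(k) img[, , k])
    } else pages <- list(img)
    ## png is read normalized; this package writes 8-bit PNG
    pages <- lapply(pages, function(p) round(p * .MAXU8))
  } else stop("unsupported image format: .", ext)
  for (p in pages) if (length(dim(p)) != 2L) stop("non-2D page in ", path)
  pages
}

#' Read a multi-channel field from a TIFF or PNG file
#'
#' Multi-page TIFFs map one page per channel. Integer pixel data are
#' returned as real values without rescaling; PNG (stored normalized by
#' the format) is mapped back to its 16-bit integer scale.
#'
#' @param path TIFF (single- or multi-page) or PNG file.
#' @param channel_names character vector naming the channels; its length
#'   must equal the page/channel count of the file.
#' @param pixel_size physical length per pixel.
#' @param field_id identifier; defaults to the file name.
#' @return a `Field`.
#' @export
read_field <- function(path, channel_names, pixel_size = 1.0,
                       field_id = basename(path)) {
  pages <- .read_pages(path)
  if (length(pages) != length(channel_names))
    stop("file has ", length(pages), " channel(s) but ",
         length(channel_names), " name(s) were given")
  names(pages) <- channel_names
  new_field(pages, pixel_size = pixel_size, field_id = field_id)
}

.write_pages <- function(pages, path) {
  for (p in pages) {
    if (any(p < 0) || any(p != round(p)))
      stop("only non-negative integer-valued images can be written losslessly")
    if (max(p) > .MAXU16)
      stop("pixel values exceed the 16-bit range (", .MAXU16, ")")
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    ok <- try(tiff::writeTIFF(lapply(pages, `/`, .MAXU16), path,
                              bits.per.sample = 16), silent = TRUE)
  } else if (ext == "png") {
    if (length(pages) != 1L) stop("PNG supports a single channel only")
    if (max(pages[[1]]) > .MAXU8)
      stop("PNG output is 8-bit; values exceed ", .MAXU8,
           " (use TIFF for 16-bit data)")
    ok <- try(png::writePNG(pages[[1]] / .MAXU8, path), silent = TRUE)
  } else stop("unsupported image format: .", ext)
  if (inherits(ok, "try-error")) stop("could not write ", path)
  invisible(path)
}

#' Write a field to disk (16-bit TIFF/PNG)
#'
#' Lossless for non-negative integer-valued intensities up to 65535,
#' which is what the camera model of [render_field()] produces.
#'
#' @param field a `Field`.
#' @param path output path (.tif/.tiff for multi-channel, .png for single).
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) .write_pages(field$channels, path)

#' Relabel a mask to consecutive labels 1..K
#'
#' Keeps the order of first appearance in column-major scan order.
#'
#' @param mask integer matrix, 0 = background.
#' @return integer matrix with labels forming `{1, ..., K}`.
#' @export
relabel_mask <- function(mask) {
  mask <- as.matrix(mask)
  storage.mode(mask) <- "integer"
  labs <- setdiff(unique(as.vector(mask)), 0L)
  if (length(labs) == 0L) return(mask)
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- mask
  fg <- mask > 0L
  out[fg] <- lut[mask[fg]]
  out
}

#' Read an integer label mask from TIFF/PNG
#'
#' Labels are relabeled to the contiguous set `{1..K}` on read.
#'
#' @param path single-page TIFF or PNG with integer labels (0 = background).
#' @return integer matrix.
#' @export
read_mask <- function(path) {
  pages <- .read_pages(path)
  if (length(pages) != 1L) stop("a label mask must be a single-page image")
  relabel_mask(pages[[1]])
}

#' Write an integer label mask as 16-bit TIFF/PNG
#' @param mask integer matrix (0 = background).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  .write_pages(list(as.matrix(mask)), path)
}

#' Read migration tracks from CSV
#'
#' The CSV must have a header with columns `track_id, frame, x, y` and
#' optionally `dt` (the frame interval, constant within a track). `x`
#' maps to image columns and `y` to image rows; this is the single point
#' where the `(x, y)` convention enters the package. Rows are sorted by
#' frame within each track; non-consecutive frames are allowed and
#' flagged in the returned track's `has_gaps` field.
#'
#' @param path CSV file.
#' @param dt frame interval (time units per frame) applied to all tracks;
#'   overridden by a `dt` column if present.
#' @param pixel_size physical length per pixel.
#' @return list of `Track` objects (see [new_track()]).
#' @export
read_tracks <- function(path, dt = NULL, pixel_size = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame", "x", "y")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  for (col in c("frame", "x", "y"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'")
  if (anyDuplicated(df[c("track_id", "frame")]))
    stop("duplicate (track_id, frame) rows in ", path)
  ids <- unique(df$track_id)
  lapply(ids, function(id) {
    sub <- df[df$track_id == id, , drop = FALSE]
    sub <- sub[order(sub$frame), , drop = FALSE]
    this_dt <- if ("dt" %in% names(sub)) sub$dt[1] else dt
    new_track(id, frame = sub$frame, x = sub$x, y = sub$y,
              dt = this_dt, pixel_size = pixel_size)
  })
}

#' Construct a migration track
#'
#' @param track_id identifier.
#' @param frame integer frame indices, strictly increasing after sorting.
#' @param x,y positions in pixels (`x` = column, `y` = row).
#' @param dt physical time per frame interval (e.g. seconds); may be `NA`
#'   if only geometric metrics are needed.
#' @param pixel_size physical length per pixel.
#' @return object of class `Track` with a `has_gaps` flag set when frames
#'   are not consecutive.
#' @export
new_track <- function(track_id, frame, x, y, dt = NA_real_, pixel_size = 1.0) {
  stopifnot(length(frame) == length(x), length(x) == length(y))
  ord <- order(frame)
  frame <- frame[ord]; x <- x[ord]; y <- y[ord]
  if (anyDuplicated(frame)) stop("duplicate frames in track ", track_id)
  structure(list(track_id = as.character(track_id),
                 frame = as.numeric(frame), x = as.numeric(x),
                 y = as.numeric(y),
                 dt = if (is.null(dt)) NA_real_ else as.numeric(dt),
                 pixel_size = as.numeric(pixel_size),
                 has_gaps = any(diff(frame) != 1)),
            class = "Track")
}

#' Write tracks to CSV (inverse of [read_tracks()])
#' @param tracks list of `Track` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  rows <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$track_id, frame = tr$frame,
               x = tr$x, y = tr$y, dt = tr$dt)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
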