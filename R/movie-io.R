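#' Calibrated image stack
#'
#' The common currency of all imaging stages: a (time, y, x) array of raw
#' intensity counts plus the physical calibration that every analysis needs.
#' Calibration is mandatory -- there are no silent defaults.
#'
#' @param frames numeric array (time, y, x) of counts.
#' @param pixel_size pixel size, um/px.
#' @param frame_interval frame interval, s.
#' @param elapsed_time elapsed-time label of this movie within a gelation
#'   run, min.
#' @param source provenance string ("synthetic" or a file path).
#' @return an object of class \code{"image_stack"}.
#' @export
image_stack <- function(frames, pixel_size, frame_interval,
                        elapsed_time = NA_real_, source = "synthetic") {
  .assert(is.array(frames) && length(dim(frames)) == 3L,
          "'frames' must be a 3-D (time, y, x) array")
  .assert(dim(frames)[1] >= 2L, "an image stack needs at least 2 frames")
  .assert(.is_pos(pixel_size), "'pixel_size' must be > 0")
  .assert(.is_pos(frame_interval), "'frame_interval' must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval,
                 elapsed_time = elapsed_time, source = source),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<image_stack> %d frames of %dx%d px | %.4g um/px | %.4g Hz | t = %s min | %s\n",
    d[1], d[2], d[3], x$pixel_size, 1 / x$frame_interval,
    format(x$elapsed_time), x$source))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

.sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write an image stack as a multi-page TIFF with a JSON sidecar
#'
#' Plain uncompressed grayscale multi-page TIFF; the physical calibration
#' goes to a sidecar JSON (\code{<path minus extension>.json}) with fields
#' \code{pixel_size_um}, \code{frame_rate_hz}, \code{elapsed_time_min}.
#' Writing is lossless: integer counts must fit the requested bit depth, and
#' out-of-range values are an error (never silently clipped).
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path output TIFF path.
#' @param bit_depth 8 or 16.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path, bit_depth = 16L) {
  .assert(inherits(stack, "image_stack"), "'stack' must be an image_stack")
  .assert(bit_depth %in% c(8L, 16L), "'bit_depth' must be 8 or 16")
  top <- 2^bit_depth - 1
  fr <- stack$frames
  if (any(fr < 0) || any(fr > top))
    stop(sprintf("write_stack: values outside [0, %d] cannot be written at %d bit (range %g..%g)",
                 top, bit_depth, min(fr), max(fr)), call. = FALSE)
  pages <- lapply(seq_len(dim(fr)[1]), function(t) fr[t, , ] / top)
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth,
                  compression = "none", reduce = TRUE)
  meta <- list(pixel_size_um = stack$pixel_size,
               frame_rate_hz = 1 / stack$frame_interval,
               elapsed_time_min = stack$elapsed_time,
               bit_depth = bit_depth,
               source = stack$source)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              null = "null", na = "null"),
             .sidecar_path(path))
  invisible(path)
}

#' Read a multi-page TIFF stack with calibration
#'
#' Frames are loaded unscaled (raw integer counts).  Calibration comes from
#' the sidecar JSON written by \code{\link{write_stack}} or from the explicit
#' arguments; if neither supplies \code{pixel_size} and \code{frame_interval}
#' this is an error naming the missing fields -- never a silent default.
#'
#' @param path TIFF path.
#' @param pixel_size optional explicit pixel size, um/px (overrides sidecar).
#' @param frame_interval optional explicit frame interval, s.
#' @param elapsed_time optional elapsed-time label, min.
#' @return an \code{\link{image_stack}}.
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval = NULL,
                       elapsed_time = NULL) {
  .assert(file.exists(path), sprintf("file not found: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L)
    stop("read_stack: single-page file; an image stack needs >= 2 frames",
         call. = FALSE)
  meta <- list()
  sc <- .sidecar_path(path)
  if (file.exists(sc)) meta <- jsonlite::fromJSON(sc)
  pixel_size <- pixel_size %||% meta$pixel_size_um
  if (is.null(frame_interval) && !is.null(meta$frame_rate_hz))
    frame_interval <- 1 / meta$frame_rate_hz
  elapsed_time <- elapsed_time %||% meta$elapsed_time_min %||% NA_real_
  missing <- c(if (is.null(pixel_size)) "pixel_size",
               if (is.null(frame_interval)) "frame_interval")
  if (length(missing))
    stop(sprintf("read_stack: missing calibration field(s): %s (no sidecar value, no explicit argument)",
                 paste(missing, collapse = ", ")), call. = FALSE)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  .assert(all(vapply(pages, function(p) nrow(p) == ny && ncol(p) == nx, TRUE)),
          "read_stack: frames have non-uniform shape")
  frames <- array(0, dim = c(length(pages), ny, nx))
  for (t in seq_along(pages)) frames[t, , ] <- pages[[t]]
  image_stack(frames, pixel_size = pixel_size,
              frame_interval = frame_interval,
              elapsed_time = if (is.null(elapsed_time)) NA_real_ else elapsed_time,
              source = path)
}

#' Crop a rectangular region of interest
#'
#' Returns a new stack (a deep copy -- never a view aliasing the parent)
#' holding the ROI, with calibration preserved.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param origin length-2 integer (row, col) of the ROI's top-left pixel,
#'   1-based.
#' @param size length-2 integer (height, width) in px.
#' @return an \code{\link{image_stack}}.
#' @export
crop_roi <- function(stack, origin, size) {
  .assert(inherits(stack, "image_stack"), "'stack' must be an image_stack")
  d <- dim(stack$frames)
  origin <- as.integer(origin); size <- as.integer(size)
  .assert(length(origin) == 2L && length(size) == 2L,
          "'origin' and 'size' must have length 2")
  .assert(all(origin >= 1L) && all(size >= 1L) &&
            origin[1] + size[1] - 1L <= d[2] &&
            origin[2] + size[2] - 1L <= d[3],
          sprintf("ROI [%d:%d, %d:%d] exceeds the %dx%d frame bounds",
                  origin[1], origin[1] + size[1] - 1L,
                  origin[2], origin[2] + size[2] - 1L, d[2], d[3]))
  sub <- stack$frames[, origin[1]:(origin[1] + size[1] - 1L),
                      origin[2]:(origin[2] + size[2] - 1L), drop = FALSE]
  image_stack(sub + 0, pixel_size = stack$pixel_size,
              frame_interval = stack$frame_interval,
              elapsed_time = stack$elapsed_time, source = stack$source)
}
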