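#' Calibrated multi-channel image
#'
#' A `calibrated_image` bundles named 2D intensity channels (row-major
#' matrices, origin at the top-left) with the physical pixel size in
#' micrometres per pixel. All channels must share the same dimensions and
#' contain finite, non-negative intensities.
#'
#' @param channels named list of numeric matrices (e.g. `dapi`, `golgi`).
#' @param pixel_size_um positive scalar, micrometres per pixel.
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(list(dapi = matrix(0, 8, 8)), pixel_size_um = 0.1)
#' dim(img$channels$dapi)
#' @export
calibrated_image <- function(channels, pixel_size_um) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(names(channels) == ""))
    stop("'channels' must be a non-empty named list of matrices")
  if (!all(vapply(channels, is.matrix, logical(1))))
    stop("every channel must be a matrix")
  dims <- vapply(channels, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all channels must share the same dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a positive scalar")
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("calibrated_image: %d x %d px, %.4g um/px, channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Split a calibrated image into its channels
#'
#' Returns the channel matrices unmodified, by name. The first analysis
#' step of both Golgi pipelines.
#'
#' @param img a [calibrated_image].
#' @param required character vector of channel names that must be present
#'   (default: all present channels).
#' @return Named list of matrices.
#' @export
split_channels <- function(img, required = names(img$channels)) {
  stopifnot(inherits(img, "calibrated_image"))
  missing <- setdiff(required, names(img$channels))
  if (length(missing))
    stop(sprintf("missing channel(s) %s; available: %s",
                 paste(missing, collapse = ", "),
                 paste(names(img$channels), collapse = ", ")))
  img$channels[required]
}

#' Write / read a calibrated image as multi-page 16-bit TIFF + JSON sidecar
#'
#' One TIFF page per channel, intensities scaled from the 16-bit range to
#' `[0,1]` as the tiff package expects; the sidecar records pixel size and
#' channel names (and optionally arbitrary ground-truth metadata).
#'
#' @param img a [calibrated_image] with intensities in `[0, 65535]`.
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @param extra optional list appended to the sidecar.
#' @return `path`, invisibly.
#' @export
write_calibrated_tiff <- function(img, path, extra = NULL) {
  stopifnot(inherits(img, "calibrated_image"))
  pages <- lapply(img$channels, function(m) pmin(pmax(m / 65535, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(list(pixel_size_um = img$pixel_size_um,
                 channel_names = names(img$channels)), extra)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibrated_tiff
#' @export
read_calibrated_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ch <- lapply(pages, function(m) m * 65535)
  names(ch) <- meta$channel_names
  calibrated_image(ch, meta$pixel_size_um)
}
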