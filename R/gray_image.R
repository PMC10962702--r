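#' Grayscale image with physical pixel size
#'
#' Lightweight container for a single-channel 2D image. Pixels are stored as a
#' numeric matrix with rows indexing y (top to bottom) and columns indexing x
#' (left to right). All user-facing coordinates in the package are 0-based,
#' `(x = column - 1, y = row - 1)`, origin at the top-left pixel.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param pixel_size Microns per pixel (default 0.108, a 60x sCMOS sampling).
#' @return An object of class `gray_image` with elements `pixels` and
#'   `pixel_size`.
#' @export
gray_image <- function(pixels, pixel_size = 0.108) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must have at least one row and one column")
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image %d x %d px, %.4g um/px, range [%.4g, %.4g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

.as_pixels <- function(img) {
  if (inherits(img, "gray_image")) img$pixels
  else if (is.matrix(img)) img
  else stop("expected a gray_image or a matrix")
}

#' Multi-channel acquisition for one imaged field
#'
#' Bundles the co-registered channel images of a single field together with
#' its plate position and acquisition tag.
#'
#' @param channels Named list of equal-dimension numeric matrices or
#'   `gray_image` objects; canonical channel names are `"dapi"`, `"dna"`,
#'   `"rna"`.
#' @param pixel_size Microns per pixel.
#' @param well Well identifier, e.g. `"A01"`.
#' @param field Field number within the well.
#' @param tag Acquisition tag: `"single"` (simultaneous protocol),
#'   `"dna_pass"` or `"rna_pass"` (sequential protocol).
#' @param meta Free-form metadata list (e.g. the applied registration vector).
#' @return An object of class `acquisition`.
#' @export
acquisition <- function(channels, pixel_size = 0.108, well = "A01",
                        field = 1L, tag = "single", meta = list()) {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels))))
    stop("channels must be a named list")
  channels <- lapply(channels, .as_pixels)
  dims <- vapply(channels, dim, integer(2L))
  if (ncol(dims) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1]))
    stop("all channels of an acquisition must share dimensions")
  if (!tag %in% c("single", "dna_pass", "rna_pass"))
    stop("tag must be one of 'single', 'dna_pass', 'rna_pass'")
  structure(list(channels = channels, pixel_size = pixel_size,
                 well = well, field = as.integer(field), tag = tag,
                 meta = meta),
            class = "acquisition")
}

#' @export
print.acquisition <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<acquisition %s f%02d [%s] %d x %d px, channels: %s>\n",
              x$well, x$field, x$tag, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract one channel of an acquisition as a gray_image
#' @param acq An `acquisition`.
#' @param channel Channel name.
#' @return A `gray_image`.
#' @export
acq_channel <- function(acq, channel) {
  stopifnot(inherits(acq, "acquisition"))
  if (!channel %in% names(acq$channels))
    stop(sprintf("acquisition %s f%02d has no '%s' channel",
                 acq$well, acq$field, channel))
  gray_image(acq$channels[[channel]], acq$pixel_size)
}

#' Read a single-channel grayscale TIFF
#'
#' Integer TIFFs (8/16-bit) are read at their native integer scale; 32-bit
#' float TIFFs are read as-is.
#'
#' @param path File path.
#' @param pixel_size Microns per pixel to attach to the image.
#' @return A `gray_image`.
#' @export
read_gray_tiff <- function(path, pixel_size = 0.108) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  px <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  gray_image(matrix(as.numeric(px), nrow(px), ncol(px)), pixel_size)
}

#' Write a grayscale image as TIFF
#'
#' @param img `gray_image` or matrix.
#' @param path Output path.
#' @param bits Bits per sample: 8 or 16 write integer TIFFs (values are
#'   clipped to the representable range), 32 writes float.
#' @return Invisibly, `path`.
#' @export
write_gray_tiff <- function(img, path, bits = 16L) {
  px <- .as_pixels(img)
  if (bits %in% c(8L, 16L)) {
    mx <- 2^bits - 1
    tiff::writeTIFF(pmin(pmax(round(px), 0), mx) / mx, path,
                    bits.per.sample = bits)
  } else if (bits == 32L) {
    storage.mode(px) <- "double"
    tiff::writeTIFF(px, path, bits.per.sample = 32L, reduce = FALSE)
  } else stop("bits must be 8, 16 or 32")
  invisible(path)
}
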