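#' Construct an image frame
#'
#' A single grayscale micrograph with pixel calibration and modality tag.
#' Pixels are stored as a numeric matrix (rows = y, columns = x) of integer
#' intensities in `[0, 2^bit_depth - 1]`.
#'
#' @param pixels Numeric matrix of intensities.
#' @param pixel_size Pixel pitch (um per pixel).
#' @param modality `"bright_field"` or `"fluorescence"`.
#' @param bit_depth 8 or 16.
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(pixels, pixel_size,
                        modality = c("bright_field", "fluorescence"),
                        bit_depth = 16) {
  modality <- match.arg(modality)
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort_validation("`pixels` must be a numeric matrix", "pixels")
  }
  if (!bit_depth %in% c(8, 16)) {
    abort_validation("`bit_depth` must be 8 or 16", "bit_depth")
  }
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  maxval <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxval)) {
    abort_validation(sprintf("`pixels` must lie in [0, %d]", maxval), "pixels")
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size, modality = modality,
         bit_depth = as.integer(bit_depth)),
    class = "image_frame"
  )
}

#' @export
print.image_frame <- function(x, ...) {
  cat(sprintf("<image_frame> %d x %d px, %g um/px, %d-bit, %s\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$bit_depth,
              x$modality))
  invisible(x)
}

#' Read / write image frames as TIFF
#'
#' Frames are stored as single-channel TIFF at the frame's bit depth.
#' `pixel_size` and `modality` are not part of the TIFF payload and must be
#' supplied on read (the simulator's manifest records them).
#'
#' @param path File path.
#' @param pixel_size Pixel pitch (um per pixel).
#' @param modality `"bright_field"` or `"fluorescence"`.
#' @param bit_depth 8 or 16.
#' @return `read_image_frame()` returns an `image_frame`;
#'   `write_image_frame()` returns `path` invisibly.
#' @export
read_image_frame <- function(path, pixel_size,
                             modality = c("bright_field", "fluorescence"),
                             bit_depth = 16) {
  modality <- match.arg(modality)
  if (!file.exists(path)) abort_input(sprintf("image not found: %s", path))
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]   # collapse grey-stored-as-RGB
  maxval <- 2^bit_depth - 1
  image_frame(round(px * maxval), pixel_size = pixel_size,
              modality = modality, bit_depth = bit_depth)
}

#' @rdname read_image_frame
#' @param frame An `image_frame`.
#' @export
write_image_frame <- function(frame, path) {
  stopifnot(inherits(frame, "image_frame"))
  maxval <- 2^frame$bit_depth - 1
  tiff::writeTIFF(frame$pixels / maxval, path,
                  bits.per.sample = frame$bit_depth)
  invisible(path)
}
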