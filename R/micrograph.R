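#' Calibrated grayscale micrograph
#'
#' A `micrograph` couples a 2-D intensity matrix (values in \[0, 1\], rows =
#' image rows) with its physical calibration in nanometres per pixel. The
#' calibration is a required user input: TEM magnification alone does not
#' determine pixel size.
#'
#' @param pixels numeric matrix of intensities in \[0, 1\], at least 64 x 64
#' @param nm_per_px positive scalar, nanometres per pixel
#' @param source_id character tag carried through results
#' @return an object of class `micrograph`
#' @export
micrograph <- function(pixels, nm_per_px, source_id = "image") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix", call. = FALSE)
  if (nrow(pixels) < 64L || ncol(pixels) < 64L)
    stop("micrograph must be at least 64 x 64 pixels", call. = FALSE)
  if (any(!is.finite(pixels)))
    stop("micrograph intensities must be finite", call. = FALSE)
  stopifnot_scalar_positive(nm_per_px, "nm_per_px")
  structure(list(pixels = pixels, nm_per_px = as.numeric(nm_per_px),
                 source_id = as.character(source_id)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph '%s': %d x %d px, %.4g nm/px>\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), x$nm_per_px))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$pixels)

#' Read a micrograph from a TIFF or PNG file
#'
#' Multi-channel images are averaged to grayscale; intensities are rescaled
#' to \[0, 1\] if stored as integers.
#'
#' @param path file path ending in .tif/.tiff or .png
#' @inheritParams micrograph
#' @return a [micrograph]
#' @export
read_micrograph <- function(path, nm_per_px, source_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(img)) == 3L) img <- apply(img, c(1L, 2L), mean)
  micrograph(img, nm_per_px, source_id)
}

#' Write a micrograph as a 16-bit grayscale TIFF
#'
#' @param img a [micrograph]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  tiff::writeTIFF(img$pixels, path, bits.per.sample = 16L)
  invisible(path)
}
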