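#' Read a portal image from 16-bit TIFF or PNG
#'
#' Pixel values are rescaled from the file's [0, 1] representation to
#' detector counts on a 16-bit scale (0..65535). The pixel pitch is not
#' stored in these formats and must be supplied (default: 0.34 mm).
#'
#' @param path image path (`.tif`, `.tiff` or `.png`).
#' @param pixelPitch mm per pixel (default 0.34).
#' @param motionAxis `"cols"` (default) or `"rows"`.
#' @return A [PortalImage-class].
#' @export
readPortalImage <- function(path, pixelPitch = 0.34, motionAxis = "cols") {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  mat <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '.", ext, "' (use TIFF or PNG)"))
  if (length(dim(mat)) == 3L) mat <- mat[, , 1L]  # first channel if colour
  PortalImage(mat * 65535, pixelPitch = pixelPitch, motionAxis = motionAxis)
}

#' Write a portal image as 16-bit grayscale TIFF
#'
#' Counts are scaled by 1/65535 and clipped to [0, 1]; counts above 65535
#' saturate.
#'
#' @param image a [PortalImage-class].
#' @param path output path (`.tif`/`.tiff`).
#' @return Invisibly, `path`.
#' @export
writePortalImage <- function(image, path) {
  stopifnot(is(image, "PortalImage"))
  mat <- pmin(pmax(image@pixels / 65535, 0), 1)
  tiff::writeTIFF(mat, path, bits.per.sample = 16L)
  invisible(path)
}
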