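# Raster ingest and export. PNG and TIFF, 8- or 16-bit, grayscale or RGB
# (RGB is collapsed to luminance). Everything internal runs on the 0-255
# scale regardless of source bit depth.

#' Read a grayscale image onto the 0-255 scale
#'
#' PNG and TIFF are supported (8- or 16-bit). Both readers return data on
#' \[0, 1\]; it is rescaled to 0-255, so 16-bit input is linearly mapped
#' onto the 8-bit scale the fusion rule's sigma threshold lives on.
#' Multi-channel images are converted to luminance (BT.601 weights
#' 0.299 R + 0.587 G + 0.114 B) with a warning.
#'
#' @param path file path (`.png`, `.tif`, `.tiff`).
#' @return numeric matrix on \[0, 255\].
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '", ext, "' for ", path,
         " (png/tif/tiff)", call. = FALSE))
  if (length(dim(x)) == 3) {
    nc <- dim(x)[3]
    if (nc >= 3) {
      warning("multi-channel image ", basename(path),
              ": converted to luminance")
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x <- x[, , 1] # gray + alpha
    }
  }
  as_intensity(x * 255, basename(path))
}

#' Write an intensity image as an 8-bit grayscale file
#'
#' Values are clamped to \[0, 255\], rounded half-up to integers, and
#' written as 8-bit PNG or TIFF.
#'
#' @param image numeric matrix on the 0-255 scale.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  x <- floor(clamp255(image) + 0.5) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stop("unsupported output format '", ext, "'", call. = FALSE))
  invisible(path)
}
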