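#' Read a 16-bit grayscale fundus image
#'
#' Supports TIFF and PNG; values are returned as an integer matrix on the
#' [0, 65535] scale regardless of the on-disk encoding.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return Integer matrix (rows x cols).
#' @export
readFundusImage <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path)
  } else {
    stop("invalid input: expected a .tif/.tiff or .png image")
  }
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # grayscale from channel 1
  matrix(as.integer(round(img * 65535)), nrow(img), ncol(img))
}

#' Write a 16-bit grayscale fundus image
#'
#' @param image Integer/numeric matrix on the [0, 65535] scale.
#' @param path Output path ending in `.tif`/`.tiff`.
#' @return `path`, invisibly.
#' @export
writeFundusImage <- function(image, path) {
  stopifnot(is.matrix(image))
  if (!grepl("\\.tiff?$", path, ignore.case = TRUE))
    stop("invalid input: 16-bit output is written as TIFF (.tif/.tiff)")
  scaled <- pmin(pmax(image, 0), 65535) / 65535
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(path)
}
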