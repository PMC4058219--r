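# Plain-text and preview output: masks and maps as CSV, magnitude images
# as 8-bit PNG.

#' Write a sampling mask (or any matrix) as CSV
#'
#' Plain 0/1 CSV without headers, one row per matrix row.
#'
#' @param mask binary matrix.
#' @param path output file.
#' @export
write_mask_csv <- function(mask, path) {
  utils::write.table(unclass(mask) * 1L, path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sampling mask from CSV
#'
#' @param path CSV file written by [write_mask_csv()].
#' @return binary `sampling_mask` matrix.
#' @export
read_mask_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  new_mask(matrix(as.integer(m != 0), nrow(m), ncol(m)))
}

#' Write a probability map or image as CSV
#'
#' @param x numeric matrix (complex input is reduced to its magnitude).
#' @param path output file.
#' @export
write_matrix_csv <- function(x, path) {
  utils::write.table(Mod(unclass(x)), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write an 8-bit PNG preview of a matrix
#'
#' Magnitudes are linearly rescaled to use the full 8-bit range.  Requires
#' the `png` package.
#'
#' @param x numeric or complex matrix.
#' @param path output file.
#' @export
write_png_preview <- function(x, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG previews")
  m <- Mod(unclass(x))
  top <- max(m)
  if (top > 0) m <- m / top
  png::writePNG(m, path)
  invisible(path)
}
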