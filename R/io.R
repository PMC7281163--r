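#' Read and write 8-bit PNG images as integer matrices/arrays
#'
#' All intermediates are stored losslessly as 8-bit PNG; gray images are
#' integer matrices and combined images integer `(h, w, 3)` arrays, with
#' values in `[0, 255]`.
#'
#' @param image Integer matrix (gray) or `(h, w, 3)` array (combined).
#' @param path File path.
#' @return Writers return `path` invisibly; readers the integer image.
#' @name png_io
NULL

#' @rdname png_io
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(image / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_gray_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m <- round(m * 255)
  storage.mode(m) <- "integer"
  m
}

#' @rdname png_io
#' @export
write_combined_png <- function(image, path) {
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' @rdname png_io
#' @export
read_combined_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3 && dim(a)[3] > 3) a <- a[, , 1:3]
  a <- round(a * 255)
  storage.mode(a) <- "integer"
  class(a) <- c("combined_image", class(a))
  a
}
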