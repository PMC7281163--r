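#' Round half away from zero toward the next integer ("round half up")
#'
#' Contrast stretching and channel averaging both quantize to 8-bit gray
#' levels with ordinary commercial rounding (127.5 -> 128), not banker's
#' rounding as in base [round()].
#'
#' @param x Numeric vector/matrix (non-negative in this package's use).
#' @return `floor(x + 0.5)`.
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Min-max contrast enhancement of a gray-level image
#'
#' Linearly rescales pixel values so the image spans the full `[0, 255]`
#' range: `p* = round((p - min) / (max - min) * 255)`, emphasizing cell
#' bodies and boundaries before channel composition.  A constant image
#' has no contrast to stretch; it is returned as all zeros with a
#' warning.
#'
#' @param image Numeric or integer matrix.
#' @return Integer matrix in `[0, 255]`; min 0 and max 255 whenever the
#'   input is non-constant.
#' @export
enhance_contrast <- function(image) {
  if (length(image) == 0) stop("image is empty")
  mn <- min(image)
  mx <- max(image)
  if (mx == mn) {
    warning("constant image: no contrast to enhance; returning zeros")
    out <- array(0L, dim = dim(image))
    return(out)
  }
  out <- round_half_up((image - mn) / (mx - mn) * 255)
  storage.mode(out) <- "integer"
  out
}

#' Compose a trap-off/trap-on pair into one three-channel change image
#'
#' Encodes the pair as a single RGB image the classifier consumes: the
#' trap-on frame in the red channel, the trap-off frame in the green
#' channel, and their per-pixel mean (rounded half up) in the blue
#' channel.  Where the cell did not move, red and green agree and the
#' pixel is gray; the deformation shows up as red/green fringes, while
#' the averaged blue channel dilutes the change and preserves the
#' background.
#'
#' @param off,on Contrast-enhanced gray-level matrices of equal shape.
#' @param channel_order `"on_red"` (default) puts the trap-on frame in
#'   red and trap-off in green; `"off_red"` swaps them (the convention
#'   used in some renderings of the encoding).  Blue is the mean either
#'   way.
#' @return Integer array `(h, w, 3)` of class `"combined_image"`.
#' @export
compose_channels <- function(off, on, channel_order = c("on_red", "off_red")) {
  channel_order <- match.arg(channel_order)
  if (!identical(dim(off), dim(on))) {
    stop("off and on images must have identical dimensions")
  }
  red <- if (channel_order == "on_red") on else off
  green <- if (channel_order == "on_red") off else on
  blue <- round_half_up((red + green) / 2)
  out <- array(c(red, green, blue), dim = c(dim(off), 3L))
  storage.mode(out) <- "integer"
  class(out) <- c("combined_image", class(out))
  out
}

#' Preprocess a cohort: contrast-enhance each frame, then compose
#'
#' Applies [enhance_contrast()] to the off and on frames of every record
#' (per-image min/max by default) and attaches the composed
#' three-channel image as `$combined`.
#'
#' @param records List of cell records.
#' @param channel_order Passed to [compose_channels()].
#' @param joint_minmax If `TRUE`, stretch the pair with a shared min/max
#'   so inter-frame brightness relations survive enhancement; default
#'   `FALSE` enhances each frame independently.
#' @return The records, each with a `$combined` array added.
#' @export
preprocess_dataset <- function(records, channel_order = "on_red",
                               joint_minmax = FALSE) {
  lapply(records, function(r) {
    if (joint_minmax) {
      both <- c(r$off_image, r$on_image)
      mn <- min(both)
      mx <- max(both)
      stretch <- function(m) {
        if (mx == mn) {
          warning("constant image pair: returning zeros")
          return(array(0L, dim = dim(m)))
        }
        out <- round_half_up((m - mn) / (mx - mn) * 255)
        storage.mode(out) <- "integer"
        out
      }
      off <- stretch(r$off_image)
      on <- stretch(r$on_image)
    } else {
      off <- enhance_contrast(r$off_image)
      on <- enhance_contrast(r$on_image)
    }
    r$combined <- compose_channels(off, on, channel_order = channel_order)
    r
  })
}
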