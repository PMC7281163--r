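#' Configuration for geometric image augmentation
#'
#' Each combined change image is expanded into `n_augment_per_cell`
#' randomly rotated, shifted, and zoomed variants plus the untouched
#' original.  Only geometric transforms are used: photometric jitter
#' would corrupt the red/green change encoding.
#'
#' @param n_augment_per_cell Number of transformed variants per cell
#'   (the original is kept in addition).
#' @param rotation_range Maximum absolute rotation, degrees; angles are
#'   drawn uniformly from `[-rotation_range, rotation_range]`.
#' @param shift_range Maximum translation as a fraction of image
#'   height/width, drawn uniformly per axis.
#' @param zoom_range `(low, high)` multiplicative scale interval; must
#'   exclude 0.
#' @param fill_mode `"nearest"` replicates edge pixels into exposed
#'   borders; `"constant"` fills with black.
#' @param seed Integer seed used by [augment_dataset()].
#' @return A validated list of class `"augment_config"`.
#' @export
augment_config <- function(n_augment_per_cell = 200, rotation_range = 30,
                           shift_range = 0.1, zoom_range = c(0.9, 1.1),
                           fill_mode = c("nearest", "constant"),
                           seed = 1L) {
  fill_mode <- match.arg(fill_mode)
  cfg <- list(n_augment_per_cell = as.integer(n_augment_per_cell),
              rotation_range = rotation_range, shift_range = shift_range,
              zoom_range = zoom_range, fill_mode = fill_mode,
              seed = as.integer(seed))
  if (cfg$n_augment_per_cell < 0) stop("n_augment_per_cell must be >= 0")
  if (length(cfg$zoom_range) != 2 || any(cfg$zoom_range <= 0)) {
    stop("zoom_range must be a positive (low, high) interval")
  }
  structure(cfg, class = "augment_config")
}

#' Apply a rigid-plus-zoom affine transform to one channel
#'
#' Inverse-maps every output pixel center through a rotation about the
#' image center, an isotropic zoom, and a translation, then samples the
#' input with nearest-neighbor interpolation so 8-bit gray levels are
#' preserved exactly.  Applying the same parameters to each channel of a
#' combined image keeps the trap-on/trap-off encoding registered.
#'
#' @param m Matrix (one channel).
#' @param angle Rotation in degrees, counter-clockwise.
#' @param shift `(dy, dx)` translation in pixels.
#' @param zoom Scale factor (> 1 enlarges).
#' @param fill_mode `"nearest"` or `"constant"` border policy.
#' @return Transformed matrix, same shape and storage mode.
#' @export
apply_affine <- function(m, angle = 0, shift = c(0, 0), zoom = 1,
                         fill_mode = "nearest") {
  h <- nrow(m)
  w <- ncol(m)
  cy <- (h + 1) / 2
  cx <- (w + 1) / 2
  th <- angle * pi / 180
  u <- matrix(seq_len(h) - cy - shift[1], h, w)
  v <- matrix(rep(seq_len(w) - cx - shift[2], each = h), h, w)
  si <- round(cy + (cos(th) * u + sin(th) * v) / zoom)
  sj <- round(cx + (-sin(th) * u + cos(th) * v) / zoom)
  if (fill_mode == "nearest") {
    si <- pmin(pmax(si, 1), h)
    sj <- pmin(pmax(sj, 1), w)
    out <- matrix(m[cbind(as.vector(si), as.vector(sj))], h, w)
  } else {
    inside <- si >= 1 & si <= h & sj >= 1 & sj <= w
    out <- matrix(0, h, w)
    out[inside] <- m[cbind(si[inside], sj[inside])]
  }
  storage.mode(out) <- storage.mode(m)
  out
}

apply_affine_combined <- function(combined, angle, shift, zoom, fill_mode) {
  out <- combined
  for (ch in 1:3) {
    out[, , ch] <- apply_affine(combined[, , ch], angle, shift, zoom,
                                fill_mode)
  }
  out
}

#' Augment one combined image
#'
#' Returns the untransformed original followed by
#' `n_augment_per_cell` random variants, each produced by one draw of
#' (rotation, shift, zoom) applied identically across the three
#' channels.  Consumes the current RNG stream; [augment_dataset()]
#' seeds it.
#'
#' @param combined A `(h, w, 3)` combined image array.
#' @param config An [augment_config()].
#' @return List of arrays of length `n_augment_per_cell + 1`; element 1
#'   is the original.
#' @export
augment_cell <- function(combined, config) {
  stopifnot(inherits(config, "augment_config"), length(dim(combined)) == 3)
  n <- config$n_augment_per_cell
  out <- vector("list", n + 1)
  out[[1]] <- combined
  h <- dim(combined)[1]
  w <- dim(combined)[2]
  for (i in seq_len(n)) {
    angle <- stats::runif(1, -config$rotation_range, config$rotation_range)
    shift <- c(stats::runif(1, -config$shift_range, config$shift_range) * h,
               stats::runif(1, -config$shift_range, config$shift_range) * w)
    zoom <- stats::runif(1, config$zoom_range[1], config$zoom_range[2])
    out[[i + 1]] <- apply_affine_combined(combined, angle, shift, zoom,
                                          config$fill_mode)
  }
  out
}

#' Augment a preprocessed cohort into an image-level dataset
#'
#' Expands every record's combined image into `n_augment_per_cell + 1`
#' images and returns them with an image-level manifest carrying the
#' parent cell id, so grouped cross-validation can keep all images of a
#' cell on one side of a fold.
#'
#' @param records Records from [preprocess_dataset()] (must carry
#'   `$combined`).
#' @param config An [augment_config()]; `config$seed` makes the
#'   expansion deterministic.
#' @return List with `images` (list of `(h, w, 3)` integer arrays) and
#'   `meta` (tibble: `image_id`, `cell_id`, `label`, `fluorescent`,
#'   `aug_index`, 0 = original).
#' @export
augment_dataset <- function(records, config) {
  stopifnot(inherits(config, "augment_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  images <- list()
  meta <- list()
  for (r in records) {
    if (is.null(r$combined)) {
      stop("record ", r$cell_id, " has no $combined image; run ",
           "preprocess_dataset() first")
    }
    variants <- augment_cell(r$combined, config)
    ids <- sprintf("%s_aug%03d", r$cell_id, seq_along(variants) - 1L)
    images <- c(images, variants)
    meta[[length(meta) + 1]] <- tibble::tibble(
      image_id = ids, cell_id = r$cell_id, label = r$label,
      fluorescent = isTRUE(r$fluorescent),
      aug_index = seq_along(variants) - 1L)
  }
  list(images = images, meta = do.call(rbind, meta))
}
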