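#' Configuration for the synthetic deformed-cell image generator
#'
#' Builds and validates the parameter set for simulating paired
#' trap-off/trap-on photomicrographs of suspended single cells.  Two cell
#' classes are simulated: an invasive (soft, strongly deforming) class and
#' a non-invasive (stiff, weakly deforming) class.  Trapping presses the
#' cell against the dish so its projected area spreads laterally; the
#' class-specific on/off area ratio distributions encode that effect.
#'
#' @param n_cells_per_class Number of cells simulated per class.
#' @param image_size Integer `(height, width)` of each rendered frame, px.
#' @param pixel_pitch Physical size of one pixel, micrometers.
#' @param radius_range `(min, max)` equivalent cell radius, micrometers.
#'   Cell bodies of 10--30 micrometer diameter correspond to `c(5, 15)`.
#' @param boundary_roughness Dimensionless amplitude of the low-order
#'   radial perturbation that makes cell outlines irregular.
#' @param deform_ratio_invasive `(mean, sd)` of the trap-on / trap-off
#'   projected-area ratio for the invasive class.  Means must be >= 1:
#'   lateral spreading under the trap never shrinks the projected area.
#' @param deform_ratio_noninvasive `(mean, sd)` of the area ratio for the
#'   non-invasive class.
#' @param noise_level Standard deviation of the additive Gaussian
#'   background noise, gray levels.
#' @param n_noise_blobs Number of bright reflected-light artifacts added
#'   to each bright-field frame (ignored in fluorescence mode, whose
#'   near-black backgrounds carry no reflection glare).
#' @param fluorescence_mode If `TRUE`, render bright cell bodies on a
#'   near-black background (calcium-dye appearance) instead of
#'   bright-field rimmed cells on a gray background.
#' @param seed Integer seed; identical seed and configuration give a
#'   bit-identical dataset.
#'
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_cells_per_class = 20,
                             image_size = c(128L, 128L),
                             pixel_pitch = 0.5,
                             radius_range = c(5, 15),
                             boundary_roughness = 0.06,
                             deform_ratio_invasive = c(1.30, 0.05),
                             deform_ratio_noninvasive = c(1.08, 0.03),
                             noise_level = 8,
                             n_noise_blobs = 3,
                             fluorescence_mode = FALSE,
                             seed = 1L) {
  cfg <- list(
    n_cells_per_class = as.integer(n_cells_per_class),
    image_size = as.integer(image_size),
    pixel_pitch = pixel_pitch,
    radius_range = radius_range,
    boundary_roughness = boundary_roughness,
    deform_ratio_invasive = deform_ratio_invasive,
    deform_ratio_noninvasive = deform_ratio_noninvasive,
    noise_level = noise_level,
    n_noise_blobs = as.integer(n_noise_blobs),
    fluorescence_mode = isTRUE(fluorescence_mode),
    seed = as.integer(seed)
  )
  if (cfg$n_cells_per_class < 0) stop("n_cells_per_class must be >= 0")
  if (length(cfg$image_size) != 2 || any(cfg$image_size < 8)) {
    stop("image_size must be (height, width) with both >= 8")
  }
  if (cfg$pixel_pitch <= 0) stop("pixel_pitch must be positive")
  if (length(cfg$radius_range) != 2 || cfg$radius_range[1] <= 0 ||
      diff(cfg$radius_range) < 0) {
    stop("radius_range must be positive (min, max) in micrometers")
  }
  for (nm in c("deform_ratio_invasive", "deform_ratio_noninvasive")) {
    dr <- cfg[[nm]]
    if (length(dr) != 2 || dr[2] < 0) stop(nm, " must be (mean, sd >= 0)")
    if (dr[1] < 1) {
      stop(nm, ": mean area ratio must be >= 1 (trapping spreads the ",
           "cell laterally; projected area never shrinks)")
    }
  }
  if (cfg$boundary_roughness < 0) stop("boundary_roughness must be >= 0")
  if (cfg$noise_level < 0) stop("noise_level must be >= 0")
  # the largest undeformed cell must fit inside the frame at this pitch
  max_r_px <- cfg$radius_range[2] / cfg$pixel_pitch
  if (2 * max_r_px > min(cfg$image_size)) {
    stop("radius_range does not fit inside image_size at this pixel_pitch")
  }
  structure(cfg, class = "synthetic_config")
}

# Shape-frame normalized radius of every pixel center for an ellipse of
# semi-axes (a, b) px rotated by `orient`, centered at (cy, cx) (1-based
# pixel-center coordinates).  Returns list(rho, theta): a pixel is inside
# the cell iff rho <= 1 + perturbation(theta).
cell_shape_field <- function(h, w, cy, cx, a, b, orient) {
  dy <- matrix(seq_len(h) - cy, h, w)
  dx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  u <- cos(orient) * dx + sin(orient) * dy
  v <- -sin(orient) * dx + cos(orient) * dy
  un <- u / a
  vn <- v / b
  list(rho = sqrt(un^2 + vn^2), theta = atan2(vn, un))
}

radial_perturbation <- function(theta, coefs, phases, roughness) {
  p <- 0
  for (m in seq_along(coefs)) {
    p <- p + coefs[m] * cos((m + 1) * theta + phases[m])
  }
  roughness * p
}

# Draw an on/off area ratio from a normal truncated at 1 (redraw).
draw_deform_ratio <- function(mean, sd) {
  if (sd == 0) return(mean)
  for (i in 1:200) {
    g <- stats::rnorm(1, mean, sd)
    if (g >= 1) return(g)
  }
  stop("could not draw a deformation ratio >= 1; check (mean, sd)")
}

#' Generate one synthetic cell record (paired off/on images)
#'
#' Renders a boundary-perturbed elliptical cell twice over one shared
#' background realization: once undeformed (trap off) and once spread
#' along its transverse axis (trap on) so that the on/off projected-area
#' ratio follows the class's deformation distribution.  Background pixels
#' outside both cell masks are identical between the two frames -- the
#' trap moves the cell boundary, not the dish.
#'
#' Consumes the current R random number stream; call [generate_dataset()]
#' for seeded, reproducible cohorts.
#'
#' @param config A [synthetic_config()].
#' @param label Class label: `1` invasive (strongly deforming), `0`
#'   non-invasive.
#' @param cell_id Identifier string stored in the record.
#'
#' @return A list of class `"cell_record"` with fields `cell_id`,
#'   `label`, `fluorescent`, `off_image`, `on_image` (integer matrices in
#'   `[0, 255]`), ground-truth masks `truth_mask_off`, `truth_mask_on`
#'   (logical matrices), and their areas `truth_area_off`,
#'   `truth_area_on` (px^2).
#' @export
generate_cell <- function(config, label, cell_id = "cell_001") {
  stopifnot(inherits(config, "synthetic_config"), label %in% c(0, 1))
  h <- config$image_size[1]
  w <- config$image_size[2]

  r_px <- stats::runif(1, config$radius_range[1], config$radius_range[2]) /
    config$pixel_pitch
  if (r_px < 2) stop("cell radius below 2 px is degenerate at this pitch")
  aspect <- stats::runif(1, 0.85, 1.18)
  a <- r_px * aspect
  b <- r_px / aspect
  orient <- stats::runif(1, 0, pi)
  coefs <- pmax(pmin(stats::rnorm(3, 0, 1), 2.5), -2.5) / (1 + seq_len(3))
  phases <- stats::runif(3, 0, 2 * pi)

  dr <- if (label == 1) config$deform_ratio_invasive else
    config$deform_ratio_noninvasive
  g <- draw_deform_ratio(dr[1], dr[2])

  # keep the deformed, roughened outline inside the frame when jittering
  extent <- max(a * g, b) * (1 + 3 * config$boundary_roughness)
  slack <- max(0, min(h, w) / 2 - extent - 1)
  jit <- min(slack, 0.04 * min(h, w))
  cy <- (h + 1) / 2 + stats::runif(1, -jit, jit)
  cx <- (w + 1) / 2 + stats::runif(1, -jit, jit)

  masks <- lapply(c(1, g), function(ascale) {
    fld <- cell_shape_field(h, w, cy, cx, a * ascale, b, orient)
    tol <- 1 + radial_perturbation(fld$theta, coefs, phases,
                                   config$boundary_roughness)
    list(inside = fld$rho <= tol, rim = fld$rho <= tol & fld$rho > 0.85 * tol)
  })

  # one background + one noise field shared by both frames
  if (config$fluorescence_mode) {
    bg <- matrix(8, h, w)
    noise <- matrix(stats::rnorm(h * w, 0, config$noise_level / 3), h, w)
    levels <- c(interior = 205, rim = 235)
  } else {
    bg <- matrix(185, h, w)
    if (config$n_noise_blobs > 0) {
      yy <- matrix(seq_len(h), h, w)
      xx <- matrix(rep(seq_len(w), each = h), h, w)
      for (i in seq_len(config$n_noise_blobs)) {
        by <- stats::runif(1, 1, h)
        bx <- stats::runif(1, 1, w)
        amp <- stats::runif(1, 25, 60)
        sg <- stats::runif(1, 1.5, 3)
        bg <- bg + amp * exp(-((yy - by)^2 + (xx - bx)^2) / (2 * sg^2))
      }
    }
    noise <- matrix(stats::rnorm(h * w, 0, config$noise_level), h, w)
    levels <- c(interior = 140, rim = 232)
  }

  render <- function(m) {
    img <- bg
    img[m$inside] <- levels[["interior"]]
    img[m$rim] <- levels[["rim"]]
    img <- round(img + noise)
    img[img < 0] <- 0
    img[img > 255] <- 255
    storage.mode(img) <- "integer"
    img
  }

  rec <- list(
    cell_id = cell_id,
    label = as.integer(label),
    fluorescent = config$fluorescence_mode,
    off_image = render(masks[[1]]),
    on_image = render(masks[[2]]),
    truth_mask_off = masks[[1]]$inside,
    truth_mask_on = masks[[2]]$inside,
    truth_area_off = sum(masks[[1]]$inside),
    truth_area_on = sum(masks[[2]]$inside)
  )
  class(rec) <- "cell_record"
  rec
}

#' Generate a balanced synthetic cohort of paired cell images
#'
#' Produces `2 * n_cells_per_class` records with unique ids and balanced
#' class labels, deterministically for a fixed `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of [generate_cell()] records; invasive (label 1) cells
#'   first, then non-invasive (label 0).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_cells_per_class
  if (n == 0) return(list())
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)
  labels <- rep(c(1L, 0L), each = n)
  lapply(seq_along(labels), function(i) {
    generate_cell(config, labels[i], cell_id = sprintf("cell_%03d", i))
  })
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a synthetic dataset to disk as PNGs plus a manifest
#'
#' Saves each frame as an 8-bit grayscale PNG (`<cell_id>_off.png`,
#' `<cell_id>_on.png`) and a `manifest.csv` with columns `cell_id`,
#' `label`, `fluorescent`, `off_path`, `on_path`, `truth_area_off`,
#' `truth_area_on`.
#'
#' @param records List of cell records from [generate_dataset()].
#' @param dir Output directory (created if absent).
#' @return The manifest as a tibble, invisibly written to
#'   `file.path(dir, "manifest.csv")`.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(records, function(r) {
    off_path <- file.path(dir, paste0(r$cell_id, "_off.png"))
    on_path <- file.path(dir, paste0(r$cell_id, "_on.png"))
    write_gray_png(r$off_image, off_path)
    write_gray_png(r$on_image, on_path)
    tibble::tibble(cell_id = r$cell_id, label = r$label,
                   fluorescent = r$fluorescent,
                   off_path = off_path, on_path = on_path,
                   truth_area_off = r$truth_area_off,
                   truth_area_on = r$truth_area_on)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset written by [write_dataset()] back into records
#'
#' @param dir Directory containing `manifest.csv` and the PNGs.
#' @return A list of `"cell_record"` objects.
#' @export
read_dataset <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"),
                        stringsAsFactors = FALSE)
  lapply(seq_len(nrow(mf)), function(i) {
    rec <- list(
      cell_id = mf$cell_id[i],
      label = as.integer(mf$label[i]),
      fluorescent = as.logical(mf$fluorescent[i]),
      off_image = read_gray_png(mf$off_path[i]),
      on_image = read_gray_png(mf$on_path[i]),
      truth_area_off = mf$truth_area_off[i],
      truth_area_on = mf$truth_area_on[i]
    )
    class(rec) <- "cell_record"
    rec
  })
}
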