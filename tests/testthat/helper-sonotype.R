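# Shared fixture builders.  Everything is generated in code at test time;
# sizes are kept small so the full suite stays fast.

# A small synthetic cohort, preprocessed and augmented, ready for the
# classifier.  Cells are ~8-16 um radius rendered at 1 um/px so they fit
# comfortably in small frames.
tiny_aug_data <- function(n_per_class = 4, image_size = c(24, 24),
                          ratio_invasive = c(1.30, 0.05),
                          ratio_noninvasive = c(1.08, 0.03),
                          n_augment = 5, seed = 1,
                          fluorescence = FALSE) {
  scfg <- synthetic_config(
    n_cells_per_class = n_per_class, image_size = image_size,
    pixel_pitch = 1.0, radius_range = c(4, min(8, min(image_size) / 2 - 4)),
    deform_ratio_invasive = ratio_invasive,
    deform_ratio_noninvasive = ratio_noninvasive,
    fluorescence_mode = fluorescence, seed = seed)
  recs <- preprocess_dataset(generate_dataset(scfg))
  augment_dataset(recs, augment_config(n_augment_per_cell = n_augment,
                                       seed = seed + 1))
}

# Minimal architecture for a given frame size.
tiny_model_config <- function(image_size = c(24, 24),
                              conv_filters = c(2L, 2L, 2L),
                              fc_width = 4L, dropout_rate = 0.5) {
  model_config(input_size = c(image_size, 3L), conv_filters = conv_filters,
               fc_width = fc_width, dropout_rate = dropout_rate)
}

# A trivially separable toy image set: bright frames (label 1) versus
# dark frames (label 0), with mild pixel noise.
toy_separable <- function(n_per_class = 6, size = 16, seed = 99) {
  withr::with_seed(seed, {
    mk <- function(level) {
      a <- array(as.integer(pmin(pmax(round(
        stats::rnorm(size * size * 3, level, 10)), 0), 255)),
        dim = c(size, size, 3))
      a
    }
    images <- c(replicate(n_per_class, mk(200), simplify = FALSE),
                replicate(n_per_class, mk(50), simplify = FALSE))
    list(images = images, labels = rep(c(1, 0), each = n_per_class))
  })
}
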