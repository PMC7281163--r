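make_cells <- function(n_per_class = 20) {
  tibble::tibble(cell_id = sprintf("cell_%03d", seq_len(2 * n_per_class)),
                 label = rep(c(1L, 0L), each = n_per_class))
}

test_that("five folds over 40 cells give 32 train / 8 test, stratified", {
  cells <- make_cells(20)
  folds <- make_folds(cells, k = 5, seed = 1)
  expect_length(folds, 5)
  all_test <- unlist(lapply(folds, `[[`, "test_cell_ids"))
  expect_setequal(all_test, cells$cell_id)
  expect_equal(anyDuplicated(all_test), 0L)
  for (f in folds) {
    expect_length(f$train_cell_ids, 32)
    expect_length(f$test_cell_ids, 8)
    expect_length(intersect(f$train_cell_ids, f$test_cell_ids), 0)
    test_labels <- cells$label[cells$cell_id %in% f$test_cell_ids]
    expect_equal(sum(test_labels == 1), 4)
    expect_equal(sum(test_labels == 0), 4)
  }
  expect_identical(make_folds(cells, k = 5, seed = 1), folds)
  expect_false(identical(make_folds(cells, k = 5, seed = 2), folds))
  expect_error(make_folds(cells, k = 41), "exceeds")
})

test_that("set metrics match the worked confusion example", {
  U <- sprintf("i%02d", 1:10)
  M <- U[1:4]            # detected
  Mstar <- U[c(1:3, 5, 6)]  # truth: |M* intersect M| = 3, |M*| = 5
  m <- compute_metrics(M, Mstar, U)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.60)
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$f1, 2 * 0.75 * 0.6 / 1.35)

  perfect <- compute_metrics(U[1:5], U[1:5], U)
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
})

test_that("degenerate prediction/truth sets warn and define metrics as 0", {
  U <- letters[1:6]
  expect_warning(m <- compute_metrics(character(0), U[1:2], U),
                 "precision")
  expect_equal(m$precision, 0)
  expect_equal(m$f1, 0)
  expect_warning(m2 <- compute_metrics(U[1:2], character(0), U), "recall")
  expect_equal(m2$recall, 0)
  expect_error(compute_metrics("z", U[1], U), "subsets")
})

test_that("metrics agree with a brute-force confusion-matrix oracle", {
  set.seed(83)
  U <- sprintf("img%03d", 1:30)
  for (i in 1:1000) {
    truth_lab <- sample(0:1, 30, replace = TRUE)
    pred_lab <- sample(0:1, 30, replace = TRUE)
    M <- U[pred_lab == 1]
    Mstar <- U[truth_lab == 1]
    tp <- sum(pred_lab == 1 & truth_lab == 1)
    fp <- sum(pred_lab == 1 & truth_lab == 0)
    fn <- sum(pred_lab == 0 & truth_lab == 1)
    tn <- sum(pred_lab == 0 & truth_lab == 0)
    suppressWarnings(m <- compute_metrics(M, Mstar, U))
    expect_identical(m$accuracy, (tp + tn) / 30)
    expect_identical(m$precision, if (tp + fp > 0) tp / (tp + fp) else 0)
    expect_identical(m$recall, if (tp + fn > 0) tp / (tp + fn) else 0)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    expect_identical(m$f1, if (p + r > 0) 2 * p * r / (p + r) else 0)
  }
})

test_that("the published best-optimizer row is internally consistent", {
  f1 <- 2 * 0.96 * 0.99 / (0.96 + 0.99)
  expect_equal(round(f1, 2), 0.97)
})

test_that("the default search grid has the documented cardinality", {
  grid <- grid_spec()
  cfgs <- grid_configurations(grid)
  counts <- table(cfgs$optimizer)
  for (opt in c("SGD", "RMSprop", "Adagrad", "Adam")) {
    expect_equal(unname(counts[opt]), 4 * 6 * 15)
  }
  expect_equal(unname(counts["Adadelta"]), 6 * 15)

  single <- grid_spec(learning_rates = 0.01, batch_sizes = 4,
                      epoch_grid = 10, optimizers = "SGD")
  expect_equal(nrow(grid_configurations(single)), 1)
  expect_error(grid_spec(optimizers = character(0)), "nonempty")
})

test_that("cross-validation keeps cells grouped and reports fold metrics", {
  aug <- tiny_aug_data(n_per_class = 4, n_augment = 4, seed = 5)
  mcfg <- tiny_model_config(c(24, 24))
  tcfg <- train_config("Adadelta", batch_size = 8, epochs = 2, seed = 5)
  cv <- cross_validate(aug, mcfg, tcfg, k = 2, seed = 5)
  expect_equal(nrow(cv$per_fold), 2)
  expect_equal(cv$per_fold$n_train_images, rep(4 * 5, 2))
  expect_equal(cv$per_fold$n_test_images, rep(4 * 5, 2))
  expect_true(all(cv$per_fold$accuracy >= 0 & cv$per_fold$accuracy <= 1))
  expect_setequal(cv$summary$metric,
                  c("loss", "accuracy", "precision", "recall", "f1"))
  # every cell is tested exactly once, and never trained on in its fold
  tested <- unlist(lapply(cv$folds, `[[`, "test_cell_ids"))
  expect_setequal(tested, unique(aug$meta$cell_id))
  for (f in cv$folds) {
    expect_length(intersect(f$train_cell_ids, f$test_cell_ids), 0)
  }
  expect_equal(sort(unique(cv$cell_level$cell_id)),
               sort(unique(aug$meta$cell_id)))
})

test_that("grid search picks the best checkpoint per optimizer", {
  aug <- tiny_aug_data(n_per_class = 3, n_augment = 3, seed = 7)
  mcfg <- tiny_model_config(c(24, 24))
  grid <- grid_spec(learning_rates = 0.0025, batch_sizes = 8L,
                    epoch_grid = c(1L, 2L), optimizers = c("Adadelta"))
  gs <- grid_search(aug, grid, mcfg, k = 2, seed = 9)
  expect_equal(nrow(gs$results), 2)  # 1 config x 2 epoch checkpoints
  expect_equal(nrow(gs$best), 1)
  best <- gs$best
  sub <- gs$results
  sub <- sub[order(-sub$accuracy, sub$loss, sub$epochs), ]
  expect_equal(best$epochs, sub$epochs[1])
  expect_equal(best$accuracy, sub$accuracy[1])
  expect_true(all(c("accuracy_sd", "f1_sd") %in% names(gs$results)))
})

test_that("cross-domain evaluation scores fluorescence images untouched", {
  aug <- tiny_aug_data(n_per_class = 3, n_augment = 3, seed = 11)
  mcfg <- tiny_model_config(c(24, 24))
  tcfg <- train_config("Adadelta", batch_size = 8, epochs = 3, seed = 11)
  m <- train(build_model(mcfg, seed = 11), aug$images, aug$meta$label, tcfg)
  params_before <- m$params

  fluor <- tiny_aug_data(n_per_class = 2, n_augment = 3, seed = 13,
                         fluorescence = TRUE)
  res <- cross_domain_evaluate(m, fluor)
  expect_s3_class(res$report, "metrics_report")
  expect_true(res$loss >= 0)
  expect_identical(m$params, params_before)
  expect_error(cross_domain_evaluate(m, list(images = list(),
                                             meta = NULL)),
               "empty")
})

test_that("accuracy recovers monotonically with the simulated effect size", {
  # cells span most of the frame so a 1.2-1.3x area change moves the
  # boundary by well over a pixel and is resolvable at this image size
  acc_at <- function(mu) {
    scfg <- synthetic_config(n_cells_per_class = 8, image_size = c(48, 48),
                             pixel_pitch = 1.0, radius_range = c(8, 15),
                             deform_ratio_invasive = c(mu, 0.02),
                             deform_ratio_noninvasive = c(1.08, 0.03),
                             seed = 17)
    recs <- preprocess_dataset(generate_dataset(scfg))
    aug <- augment_dataset(recs, augment_config(n_augment_per_cell = 15,
                                                seed = 18))
    mcfg <- model_config(input_size = c(48, 48, 3),
                         conv_filters = c(4L, 8L, 8L), fc_width = 16L)
    tcfg <- train_config("Adadelta", batch_size = 4, epochs = 8, seed = 17)
    cv <- cross_validate(aug, mcfg, tcfg, k = 4, seed = 17)
    cv$summary$mean[cv$summary$metric == "accuracy"]
  }
  accs <- vapply(c(1.08, 1.19, 1.30), acc_at, numeric(1))
  # non-decreasing within simulation noise, and the strong effect is
  # clearly recovered relative to the null
  expect_gt(accs[2], accs[1] - 0.1)
  expect_gt(accs[3], accs[2] - 0.1)
  expect_gt(accs[3], accs[1] + 0.1)
})
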