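#' Stratified grouped k-fold splits at the cell level
#'
#' Partitions cells (not images) into k folds so every cell is a test
#' cell exactly once, no cell ever contributes images to both sides of a
#' fold, and each test set carries equal class counts whenever the
#' totals allow.  Within each class, cells are shuffled once
#' (deterministically for a fixed seed) and dealt round-robin to folds.
#'
#' @param cells Tibble/data.frame with columns `cell_id` and `label`, or
#'   a list of cell records.
#' @param k Number of folds (>= 2).
#' @param seed Shuffle seed.
#' @return List of `k` lists with `fold_index` (0-based),
#'   `train_cell_ids`, `test_cell_ids`.
#' @export
make_folds <- function(cells, k = 5, seed = 1L) {
  if (is.list(cells) && !is.data.frame(cells) &&
      inherits(cells[[1]], "cell_record")) {
    cells <- tibble::tibble(
      cell_id = vapply(cells, `[[`, character(1), "cell_id"),
      label = vapply(cells, `[[`, integer(1), "label"))
  }
  cells <- unique(tibble::as_tibble(cells[, c("cell_id", "label")]))
  n <- nrow(cells)
  if (k < 2) stop("k must be >= 2")
  if (k > n) stop("k = ", k, " exceeds the number of cells (", n, ")")
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  assignment <- integer(n)
  for (cl in sort(unique(cells$label))) {
    idx <- which(cells$label == cl)
    idx <- idx[sample.int(length(idx))]
    assignment[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(fold_index = f - 1L,
         train_cell_ids = cells$cell_id[assignment != f],
         test_cell_ids = cells$cell_id[assignment == f])
  })
}

#' Set-based classification metrics (accuracy, precision, recall, F1)
#'
#' With `M` the detected-invasive set, `M*` the truly invasive set, and
#' `U` the universe of scored items:
#' `a = (|M* \U2229 M| + |(M* \U222A M)^c|) / |U|`,
#' `p = |M* \U2229 M| / |M|`, `r = |M* \U2229 M| / |M*|`,
#' `F1 = 2pr / (p + r)`.  Empty `M` (or `M*`) yields precision (recall)
#' 0 with a warning; `p + r = 0` yields F1 = 0.
#'
#' @param detected Ids predicted invasive (`M`).
#' @param truth Ids truly invasive (`M*`).
#' @param universe All scored ids (`U`); `detected` and `truth` must be
#'   subsets.
#' @return A list of class `"metrics_report"`: `accuracy`, `precision`,
#'   `recall`, `f1`, and the counts `n_detected`, `n_truth`,
#'   `n_hit`, `n_universe`.
#' @export
compute_metrics <- function(detected, truth, universe) {
  detected <- unique(detected)
  truth <- unique(truth)
  universe <- unique(universe)
  if (!all(detected %in% universe) || !all(truth %in% universe)) {
    stop("detected and truth must be subsets of the universe")
  }
  hit <- length(intersect(detected, truth))
  outside <- length(universe) - length(union(detected, truth))
  a <- (hit + outside) / length(universe)
  if (length(detected) == 0) {
    warning("no detections: precision set to 0")
    p <- 0
  } else {
    p <- hit / length(detected)
  }
  if (length(truth) == 0) {
    warning("no true positives in universe: recall set to 0")
    r <- 0
  } else {
    r <- hit / length(truth)
  }
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(list(accuracy = a, precision = p, recall = r, f1 = f1,
                 n_detected = length(detected), n_truth = length(truth),
                 n_hit = hit, n_universe = length(universe)),
            class = "metrics_report")
}

metrics_row <- function(m, loss = NA_real_) {
  tibble::tibble(loss = loss, accuracy = m$accuracy,
                 precision = m$precision, recall = m$recall, f1 = m$f1)
}

# Image-level metrics + loss from scores on a test manifest.
score_to_metrics <- function(meta, scores) {
  detected <- meta$image_id[decide_label(scores) == 1]
  truth <- meta$image_id[meta$label == 1]
  m <- compute_metrics(detected, truth, meta$image_id)
  list(report = m, loss = bce_loss(meta$label, scores))
}

#' Grouped five-fold cross-validation of the CNN classifier
#'
#' For each fold, a fresh model is initialized and trained on all images
#' whose parent cell is in the fold's training set, then scored on the
#' held-out cells' images.  Metrics are image-level (every augmented
#' image is scored independently); a cell-level majority-vote summary is
#' also returned as a secondary, clearly separate report.  A leakage
#' assertion verifies that no parent cell id appears on both sides of
#' any fold.
#'
#' @param aug_data Augmented dataset from [augment_dataset()].
#' @param model_config A [model_config()] matching the image size.
#' @param train_cfg A [train_config()].
#' @param k Number of folds.
#' @param seed Seed controlling fold assignment and per-fold model
#'   initialization/training (per-fold seeds are derived from it).
#' @param track_validation If `TRUE`, each fold's test set is also
#'   evaluated at every epoch so per-epoch learning curves can be drawn.
#' @return List with `per_fold` (tibble: fold, loss, accuracy,
#'   precision, recall, f1, n_train_images, n_test_images), `summary`
#'   (mean and sd per metric), `cell_level` (majority-vote tibble),
#'   `folds`, and `histories`.
#' @export
cross_validate <- function(aug_data, model_config, train_cfg, k = 5,
                           seed = 1L, track_validation = FALSE) {
  meta <- aug_data$meta
  cells <- unique(meta[, c("cell_id", "label")])
  folds <- make_folds(cells, k = k, seed = seed)
  per_fold <- list()
  cell_rows <- list()
  histories <- list()
  for (f in seq_along(folds)) {
    fold <- folds[[f]]
    stopifnot(length(intersect(fold$train_cell_ids,
                               fold$test_cell_ids)) == 0)
    tr <- which(meta$cell_id %in% fold$train_cell_ids)
    te <- which(meta$cell_id %in% fold$test_cell_ids)
    # leakage check on the image manifests themselves
    stopifnot(length(intersect(meta$cell_id[tr], meta$cell_id[te])) == 0)
    model <- build_model(model_config, seed = seed + f)
    tcfg <- train_cfg
    tcfg$seed <- as.integer(seed + 1000L + f)
    validation <- if (track_validation) {
      list(images = aug_data$images[te], labels = meta$label[te])
    } else NULL
    model <- train(model, aug_data$images[tr], meta$label[tr], tcfg,
                   validation = validation)
    scores <- predict(model, aug_data$images[te])
    sm <- score_to_metrics(meta[te, ], scores)
    per_fold[[f]] <- cbind(tibble::tibble(fold = f - 1L),
                           metrics_row(sm$report, sm$loss),
                           tibble::tibble(n_train_images = length(tr),
                                          n_test_images = length(te)))
    histories[[f]] <- model$history
    votes <- tapply(decide_label(scores), meta$cell_id[te],
                    function(v) as.integer(mean(v) > 0.5))
    truth_lab <- tapply(meta$label[te], meta$cell_id[te], `[`, 1)
    cell_rows[[f]] <- tibble::tibble(fold = f - 1L,
                                     cell_id = names(votes),
                                     vote = as.integer(votes),
                                     label = as.integer(truth_lab))
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("loss", "accuracy", "precision", "recall", "f1")
  summary <- tibble::tibble(
    metric = metric_cols,
    mean = vapply(metric_cols, function(c) mean(per_fold[[c]]), numeric(1)),
    sd = vapply(metric_cols, function(c) stats::sd(per_fold[[c]]),
                numeric(1)))
  list(per_fold = per_fold, summary = summary,
       cell_level = do.call(rbind, cell_rows), folds = folds,
       histories = histories)
}

#' Hyper-parameter grid for the optimizer search
#'
#' Default grids follow the search design: learning rates from 0.00025
#' to 0.25 in x10 steps, batch sizes 1 to 32 in x2 steps, epochs 20 to
#' 300 in +20 steps, over the five optimizers.  Adadelta's learning rate
#' is fixed at 1.00 and is not searched.
#'
#' @param learning_rates,batch_sizes,epoch_grid,optimizers Grid axes.
#' @return A list of class `"grid_spec"`.
#' @export
grid_spec <- function(learning_rates = c(0.00025, 0.0025, 0.025, 0.25),
                      batch_sizes = c(1L, 2L, 4L, 8L, 16L, 32L),
                      epoch_grid = seq(20L, 300L, by = 20L),
                      optimizers = c("SGD", "RMSprop", "Adagrad",
                                     "Adadelta", "Adam")) {
  if (length(learning_rates) == 0 || length(batch_sizes) == 0 ||
      length(epoch_grid) == 0 || length(optimizers) == 0) {
    stop("grid axes must be nonempty")
  }
  structure(list(learning_rates = learning_rates,
                 batch_sizes = as.integer(batch_sizes),
                 epoch_grid = as.integer(epoch_grid),
                 optimizers = optimizers),
            class = "grid_spec")
}

#' Enumerate the training configurations of a grid
#'
#' Adadelta contributes one (fixed) learning rate, the other optimizers
#' the full learning-rate axis; every configuration is crossed with the
#' batch-size and epoch axes.
#'
#' @param grid A [grid_spec()].
#' @return Tibble with columns `optimizer`, `learning_rate`,
#'   `batch_size`, `epochs`.
#' @export
grid_configurations <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  rows <- lapply(grid$optimizers, function(opt) {
    lrs <- if (opt == "Adadelta") 1 else grid$learning_rates
    expand.grid(optimizer = opt, learning_rate = lrs,
                batch_size = grid$batch_sizes, epochs = grid$epoch_grid,
                stringsAsFactors = FALSE)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Exhaustive optimizer/hyper-parameter grid search
#'
#' Evaluates every (optimizer, learning rate, batch size) combination by
#' grouped k-fold cross-validation, training each fold once to the
#' largest epoch of the grid and reading the validation metrics at every
#' epoch checkpoint in the grid (rather than retraining per epoch
#' value).  The best configuration per optimizer is the one with the
#' highest mean validation accuracy, ties broken by lower mean
#' validation loss, then by smaller epoch count.
#'
#' @param aug_data Augmented dataset from [augment_dataset()].
#' @param grid A [grid_spec()].
#' @param model_cfg A [model_config()].
#' @param k Folds.
#' @param seed Seed (folds are shared across configurations).
#' @return List with `results` (long tibble: one row per configuration
#'   x epoch checkpoint, with mean and sd of loss, accuracy, precision,
#'   recall, F1 across folds) and `best` (one row per optimizer).
#' @export
grid_search <- function(aug_data, grid, model_cfg, k = 5, seed = 1L) {
  stopifnot(inherits(grid, "grid_spec"))
  meta <- aug_data$meta
  cells <- unique(meta[, c("cell_id", "label")])
  folds <- make_folds(cells, k = k, seed = seed)
  max_ep <- max(grid$epoch_grid)
  combos <- unique(grid_configurations(grid)[, c("optimizer",
                                                 "learning_rate",
                                                 "batch_size")])
  results <- list()
  for (ci in seq_len(nrow(combos))) {
    opt <- combos$optimizer[ci]
    lr <- combos$learning_rate[ci]
    bs <- combos$batch_size[ci]
    fold_metrics <- list()  # [fold][epoch] -> metric row
    for (f in seq_along(folds)) {
      fold <- folds[[f]]
      tr <- which(meta$cell_id %in% fold$train_cell_ids)
      te <- which(meta$cell_id %in% fold$test_cell_ids)
      model <- build_model(model_cfg, seed = seed + f)
      tcfg <- train_config(optimizer = opt, learning_rate = lr,
                           batch_size = bs, epochs = max_ep,
                           seed = seed + 1000L + f)
      model <- train(model, aug_data$images[tr], meta$label[tr], tcfg,
                     validation = list(images = aug_data$images[te],
                                       labels = meta$label[te]),
                     eval_epochs = grid$epoch_grid,
                     keep_val_scores = TRUE)
      rows <- lapply(grid$epoch_grid, function(ep) {
        vs <- model$val_scores[[as.character(ep)]]
        sm <- score_to_metrics(meta[te, ], vs)
        cbind(tibble::tibble(epochs = ep, fold = f - 1L),
              metrics_row(sm$report, sm$loss))
      })
      fold_metrics[[f]] <- do.call(rbind, rows)
    }
    all_rows <- do.call(rbind, fold_metrics)
    for (ep in grid$epoch_grid) {
      sub <- all_rows[all_rows$epochs == ep, ]
      results[[length(results) + 1]] <- tibble::tibble(
        optimizer = opt, learning_rate = lr, batch_size = bs,
        epochs = ep,
        loss = mean(sub$loss), loss_sd = stats::sd(sub$loss),
        accuracy = mean(sub$accuracy), accuracy_sd = stats::sd(sub$accuracy),
        precision = mean(sub$precision),
        precision_sd = stats::sd(sub$precision),
        recall = mean(sub$recall), recall_sd = stats::sd(sub$recall),
        f1 = mean(sub$f1), f1_sd = stats::sd(sub$f1))
    }
  }
  results <- do.call(rbind, results)
  best <- do.call(rbind, lapply(unique(results$optimizer), function(opt) {
    sub <- results[results$optimizer == opt, ]
    sub <- sub[order(-sub$accuracy, sub$loss, sub$epochs), ]
    sub[1, ]
  }))
  list(results = results, best = best)
}

#' Cross-domain evaluation on fluorescence images
#'
#' Scores a model trained on bright-field images against an augmented
#' fluorescence-mode dataset, with no retraining, probing whether the
#' change encoding generalizes across imaging appearance.
#'
#' @param model A trained `"sono_cnn"`.
#' @param fluor_data Augmented fluorescence dataset (from
#'   [augment_dataset()]), preprocessed identically to the training
#'   images.
#' @return List with `report` (a `"metrics_report"`), `loss`, and
#'   `metrics` (one-row tibble).
#' @export
cross_domain_evaluate <- function(model, fluor_data) {
  if (is.null(fluor_data$meta) || nrow(fluor_data$meta) == 0) {
    stop("fluorescent dataset is empty")
  }
  scores <- predict(model, fluor_data$images)
  sm <- score_to_metrics(fluor_data$meta, scores)
  list(report = sm$report, loss = sm$loss,
       metrics = metrics_row(sm$report, sm$loss))
}
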