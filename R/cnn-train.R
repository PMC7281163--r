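#' Training configuration (optimizer, learning rate, batch size, epochs)
#'
#' @param optimizer One of `"SGD"`, `"RMSprop"`, `"Adagrad"`,
#'   `"Adadelta"`, `"Adam"`.
#' @param learning_rate Learning rate rho.  Adadelta rescales its own
#'   steps from accumulated statistics and its reference formulation
#'   recommends an initial rate of 1.00, so for Adadelta the rate is
#'   forced to 1 (with a message if another value was requested).
#' @param batch_size Batch size beta: how frequently the weights are
#'   updated (every `batch_size` training images).
#' @param epochs Number of full passes (epsilon) over the training set.
#' @param seed Seed for shuffling and dropout during training.
#' @return A validated list of class `"train_config"`.
#' @export
train_config <- function(optimizer = c("Adadelta", "SGD", "RMSprop",
                                       "Adagrad", "Adam"),
                         learning_rate = NULL, batch_size = 16L,
                         epochs = 20L, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (optimizer == "Adadelta") {
    if (!is.null(learning_rate) && learning_rate != 1) {
      message("Adadelta uses a fixed initial learning rate of 1.00; ",
              "ignoring learning_rate = ", learning_rate)
    }
    learning_rate <- 1
  } else if (is.null(learning_rate)) {
    learning_rate <- 0.0025
  }
  cfg <- list(optimizer = optimizer, learning_rate = learning_rate,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs), seed = as.integer(seed))
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$batch_size < 1) stop("batch_size must be >= 1")
  if (cfg$epochs < 0) stop("epochs must be >= 0")
  structure(cfg, class = "train_config")
}

# Per-parameter optimizer state and update rules.  Each method uses the
# canonical constants of its original formulation: RMSprop decay 0.9,
# Adagrad/RMSprop/Adam epsilon 1e-8, Adadelta decay 0.95 / epsilon 1e-6,
# Adam beta1 0.9 / beta2 0.999 with bias correction.
make_opt_state <- function(optimizer, params) {
  zeros <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  switch(optimizer,
    SGD = list(),
    RMSprop = list(acc = zeros),
    Adagrad = list(acc = zeros),
    Adadelta = list(acc_g = zeros, acc_d = zeros),
    Adam = list(m = zeros, v = zeros, t = 0)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# keep updated parameters in the exact shape of the originals (biases are
# plain vectors; a stray 1-d dim attribute breaks matrix arithmetic)
shape_like <- function(x, ref) {
  if (is.null(dim(ref))) return(as.vector(x))
  dim(x) <- dim(ref)
  x
}

opt_step <- function(optimizer, lr, params, grads, state) {
  nm <- names(params)
  orig <- params
  switch(optimizer,
    SGD = {
      for (k in nm) params[[k]] <- params[[k]] - lr * grads[[k]]
    },
    RMSprop = {
      for (k in nm) {
        state$acc[[k]] <- 0.9 * state$acc[[k]] + 0.1 * grads[[k]]^2
        params[[k]] <- params[[k]] -
          lr * grads[[k]] / sqrt(state$acc[[k]] + 1e-8)
      }
    },
    Adagrad = {
      for (k in nm) {
        state$acc[[k]] <- state$acc[[k]] + grads[[k]]^2
        params[[k]] <- params[[k]] -
          lr * grads[[k]] / (sqrt(state$acc[[k]]) + 1e-8)
      }
    },
    Adadelta = {
      for (k in nm) {
        state$acc_g[[k]] <- 0.95 * state$acc_g[[k]] + 0.05 * grads[[k]]^2
        step <- -sqrt(state$acc_d[[k]] + 1e-6) /
          sqrt(state$acc_g[[k]] + 1e-6) * grads[[k]]
        state$acc_d[[k]] <- 0.95 * state$acc_d[[k]] + 0.05 * step^2
        params[[k]] <- params[[k]] + lr * step
      }
    },
    Adam = {
      state$t <- state$t + 1
      bc1 <- 1 - 0.9^state$t
      bc2 <- 1 - 0.999^state$t
      for (k in nm) {
        state$m[[k]] <- 0.9 * state$m[[k]] + 0.1 * grads[[k]]
        state$v[[k]] <- 0.999 * state$v[[k]] + 0.001 * grads[[k]]^2
        params[[k]] <- params[[k]] -
          lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + 1e-8)
      }
    }
  )
  for (k in nm) params[[k]] <- shape_like(params[[k]], orig[[k]])
  list(params = params, state = state)
}

#' Train the shallow CNN by mini-batch back-propagation
#'
#' Runs `epochs` passes over the training images, updating the weights
#' with the configured optimizer after every `batch_size` images
#' (gradient of the binary cross-entropy loss, labels coded 1 =
#' invasive).  With `epochs = 0` the model is returned at its
#' initialization.  Training is deterministic for a fixed
#' `config$seed` under single-threaded execution.
#'
#' @param model A `"sono_cnn"` from [build_model()].
#' @param images Training images (list of `(h, w, 3)` arrays).
#' @param labels Binary label vector, one per image.
#' @param config A [train_config()].
#' @param validation Optional `list(images =, labels =)` evaluated at
#'   checkpoint epochs.
#' @param eval_epochs Epochs at which the validation set is evaluated;
#'   `NULL` means every epoch.
#' @param keep_val_scores If `TRUE`, retain the validation score vector
#'   at every evaluated epoch (used by the grid search to report
#'   checkpoint metrics without retraining).
#' @return The model with trained `params`, a `history` tibble (epoch,
#'   train_loss, train_acc, val_loss, val_acc), and, if requested,
#'   `val_scores` (named list by epoch).
#' @export
train <- function(model, images, labels, config, validation = NULL,
                  eval_epochs = NULL, keep_val_scores = FALSE) {
  stopifnot(inherits(model, "sono_cnn"), inherits(config, "train_config"))
  n <- length(labels)
  if (n == 0) stop("empty training set")
  x4 <- images_to_array(images, model$config$input_size)
  if (dim(x4)[4] != n) stop("images and labels disagree in length")
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) stop("labels must be coded 0/1")

  vx <- NULL
  if (!is.null(validation)) {
    vx <- images_to_array(validation$images, model$config$input_size)
    vy <- as.numeric(validation$labels)
  }
  if (is.null(eval_epochs)) eval_epochs <- seq_len(config$epochs)

  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(config$seed)

  params <- model$params
  state <- make_opt_state(config$optimizer, params)
  hist <- vector("list", config$epochs)
  val_scores <- list()

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    loss_sum <- 0
    correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      xb <- x4[, , , idx, drop = FALSE]
      yb <- y[idx]
      model$params <- params
      fwd <- cnn_forward(model, xb, training = TRUE)
      grads <- cnn_backward(model, fwd$cache, fwd$prob, yb)
      upd <- opt_step(config$optimizer, config$learning_rate, params,
                      grads, state)
      params <- upd$params
      state <- upd$state
      loss_sum <- loss_sum + bce_loss(yb, fwd$prob) * length(idx)
      correct <- correct + sum(decide_label(fwd$prob) == yb)
    }
    model$params <- params
    vl <- NA_real_
    va <- NA_real_
    if (!is.null(vx) && ep %in% eval_epochs) {
      vs <- as.vector(cnn_forward(model, vx, training = FALSE)$prob)
      vl <- bce_loss(vy, vs)
      va <- mean(decide_label(vs) == vy)
      if (keep_val_scores) val_scores[[as.character(ep)]] <- vs
    }
    hist[[ep]] <- tibble::tibble(epoch = ep,
                                 train_loss = loss_sum / n,
                                 train_acc = correct / n,
                                 val_loss = vl, val_acc = va)
  }
  model$params <- params
  model$history <- if (config$epochs > 0) do.call(rbind, hist) else
    tibble::tibble(epoch = integer(), train_loss = numeric(),
                   train_acc = numeric(), val_loss = numeric(),
                   val_acc = numeric())
  if (keep_val_scores) model$val_scores <- val_scores
  model$train_config <- config
  model
}

#' Save / load a model checkpoint
#'
#' Weights are written as a flat JSON object (arrays with their
#' dimensions) with the architecture and training configuration
#' alongside, so checkpoints are plain text and portable.
#'
#' @param model A `"sono_cnn"`.
#' @param path Output file path (JSON).
#' @return `save_model`: `path`, invisibly.  `load_model`: the model.
#' @export
save_model <- function(model, path) {
  obj <- list(
    config = unclass(model$config),
    train_config = if (!is.null(model$train_config))
      unclass(model$train_config) else NULL,
    params = lapply(model$params, function(p) {
      list(dim = dim(p) %||% length(p), data = as.vector(p))
    })
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, obj$config[c("input_size", "conv_filters",
                                            "kernel_size", "stride",
                                            "pool_size", "fc_width",
                                            "dropout_rate")])
  model <- build_model(cfg, seed = 0L)
  model$params <- lapply(obj$params, function(p) {
    if (length(p$dim) > 1) array(p$data, dim = p$dim) else
      if (!is.null(names(p$data))) unname(p$data) else p$data
  })
  # restore matrix shape for fc weights
  for (k in c("fc1_w", "fc2_w")) {
    d <- obj$params[[k]]$dim
    model$params[[k]] <- matrix(obj$params[[k]]$data, d[1], d[2])
  }
  model
}
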