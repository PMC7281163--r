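#' Weighted summation of an image patch with a convolutional filter
#'
#' The primitive a convolutional filter computes at one position: the
#' elementwise product of a k x k patch with a k x k weight matrix,
#' summed.  A horizontal-edge filter with rows (1,1,1), (0,0,0),
#' (-1,-1,-1) contrasts upper pixels against lower ones: on a patch with
#' rows (0,0,0), (0,0,0), (10,10,10) it returns -30, and on a uniform
#' patch of 10s it returns 0.
#'
#' @param patch,filter Numeric matrices of identical shape.
#' @return The scalar sum of the elementwise products.
#' @export
weighted_summation <- function(patch, filter) {
  if (!identical(dim(patch), dim(filter))) {
    stop("patch and filter must have identical dimensions")
  }
  sum(patch * filter)
}

#' Architecture configuration for the shallow CNN
#'
#' Fixes the layer layout of the classifier: three 2-D convolutional
#' layers (rectifier activations, zero "same" padding), each followed by
#' one 2 x 2 max-pooling layer; the pooled maps are flattened into a
#' fully connected rectifier layer with dropout 0.5, then a single
#' sigmoid output unit scoring the invasive class in `[0, 1]`.
#'
#' @param input_size `(height, width, 3)` of the combined input images.
#' @param conv_filters Filter counts of the three convolutional layers.
#'   The first layer uses thirty-two 3 x 3 filters by default; the
#'   deeper widths are tunable.
#' @param kernel_size Side length of the square filters.
#' @param stride Convolution stride (step size, in pixels, between
#'   filter applications).
#' @param pool_size Max-pooling window/stride.
#' @param fc_width Units in the first fully connected layer.
#' @param dropout_rate Dropout probability after the first fully
#'   connected layer.
#' @return A validated list of class `"model_config"`.
#' @export
model_config <- function(input_size = c(128L, 128L, 3L),
                         conv_filters = c(32L, 64L, 128L),
                         kernel_size = 3L, stride = 1L, pool_size = 2L,
                         fc_width = 128L, dropout_rate = 0.5) {
  cfg <- list(input_size = as.integer(input_size),
              conv_filters = as.integer(conv_filters),
              kernel_size = as.integer(kernel_size),
              stride = as.integer(stride),
              pool_size = as.integer(pool_size),
              fc_width = as.integer(fc_width),
              dropout_rate = dropout_rate)
  if (length(cfg$input_size) != 3 || cfg$input_size[3] != 3) {
    stop("input_size must be (height, width, 3)")
  }
  if (length(cfg$conv_filters) != 3 || any(cfg$conv_filters < 1)) {
    stop("exactly three convolutional layers are required")
  }
  if (cfg$kernel_size < 1 || cfg$stride < 1 || cfg$pool_size < 2) {
    stop("kernel_size/stride must be >= 1 and pool_size >= 2")
  }
  if (cfg$fc_width < 1) stop("fc_width must be >= 1")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  dims <- conv_stack_dims(cfg)
  if (any(dims$final < 1)) {
    stop("input too small for three convolution + pooling stages")
  }
  structure(cfg, class = "model_config")
}

# Spatial dimensions after each conv ("same" padding) + pool stage.
conv_stack_dims <- function(cfg) {
  h <- cfg$input_size[1]
  w <- cfg$input_size[2]
  k <- cfg$kernel_size
  p <- (k - 1) %/% 2
  per_stage <- list()
  for (l in 1:3) {
    h <- (h + 2 * p - k) %/% cfg$stride + 1
    w <- (w + 2 * p - k) %/% cfg$stride + 1
    h <- h %/% cfg$pool_size
    w <- w %/% cfg$pool_size
    per_stage[[l]] <- c(h, w)
  }
  list(per_stage = per_stage, final = c(h, w),
       flat = h * w * cfg$conv_filters[3])
}

#' Build an untrained shallow CNN with reproducible initial weights
#'
#' Initializes all filter banks and fully connected weights with
#' variance-scaled Gaussian draws (He scaling for the rectifier layers,
#' 1/fan-in for the sigmoid output) and zero biases, from a fixed seed:
#' identical seeds give bit-identical initial weights.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight initialization.
#' @return A list of class `"sono_cnn"` with `config`, flat parameter
#'   list `params`, and `flat_dim`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- globalenv()$.Random.seed
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  k <- config$kernel_size
  chans <- c(config$input_size[3], config$conv_filters)
  params <- list()
  for (l in 1:3) {
    fan_in <- k * k * chans[l]
    params[[paste0("conv", l, "_w")]] <-
      array(stats::rnorm(k * k * chans[l] * chans[l + 1],
                         sd = sqrt(2 / fan_in)),
            dim = c(k, k, chans[l], chans[l + 1]))
    params[[paste0("conv", l, "_b")]] <- numeric(chans[l + 1])
  }
  flat <- conv_stack_dims(config)$flat
  params$fc1_w <- matrix(stats::rnorm(flat * config$fc_width,
                                      sd = sqrt(2 / flat)),
                         flat, config$fc_width)
  params$fc1_b <- numeric(config$fc_width)
  params$fc2_w <- matrix(stats::rnorm(config$fc_width,
                                      sd = sqrt(1 / config$fc_width)),
                         config$fc_width, 1)
  params$fc2_b <- numeric(1)
  structure(list(config = config, params = params, flat_dim = flat),
            class = "sono_cnn")
}

#' Total number of trainable parameters of a model
#'
#' @param model A `"sono_cnn"`.
#' @return Integer count of weights plus biases over all layers.
#' @export
count_params <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass on a (H, W, 3, N) array of inputs scaled to [0, 1].
# In training mode, dropout consumes the RNG stream (inverted dropout);
# at inference dropout is disabled, so predictions are deterministic and
# independent of batch composition.
cnn_forward <- function(model, x4, training = FALSE) {
  p <- model$params
  cfg <- model$config
  cache <- list(x = x4)
  a <- x4
  for (l in 1:3) {
    z <- conv2d_forward_cpp(a, p[[paste0("conv", l, "_w")]],
                            p[[paste0("conv", l, "_b")]], cfg$stride)
    r <- relu(z)
    pooled <- maxpool_forward_cpp(r, cfg$pool_size)
    cache[[paste0("a", l)]] <- a
    cache[[paste0("z", l)]] <- z
    cache[[paste0("r", l)]] <- r
    cache[[paste0("idx", l)]] <- pooled$idx
    cache[[paste0("rdim", l)]] <- dim(r)
    a <- pooled$y
  }
  n <- dim(a)[4]
  f <- matrix(a, model$flat_dim, n)
  f <- t(f)
  z1 <- sweep(f %*% p$fc1_w, 2, p$fc1_b, "+")
  r1 <- relu(z1)
  if (training && cfg$dropout_rate > 0) {
    keep <- 1 - cfg$dropout_rate
    mask <- matrix((stats::runif(length(r1)) < keep) / keep,
                   nrow(r1), ncol(r1))
    h1 <- r1 * mask
  } else {
    mask <- NULL
    h1 <- r1
  }
  z2 <- h1 %*% p$fc2_w + p$fc2_b
  prob <- as.vector(sigmoid(z2))
  cache$f <- f
  cache$fc_z1 <- z1
  cache$fc_mask <- mask
  cache$fc_h1 <- h1
  cache$pooled_dim <- dim(a)
  list(prob = prob, cache = cache)
}

# Backward pass for sigmoid output + binary cross-entropy: the gradient
# at the output pre-activation is (prob - y) / N.  Returns gradients in
# the same flat layout as model$params.
cnn_backward <- function(model, cache, prob, y) {
  p <- model$params
  cfg <- model$config
  n <- length(y)
  grads <- list()
  dz2 <- matrix((prob - y) / n, n, 1)
  grads$fc2_w <- t(cache$fc_h1) %*% dz2
  grads$fc2_b <- sum(dz2)
  dh1 <- dz2 %*% t(p$fc2_w)
  if (!is.null(cache$fc_mask)) dh1 <- dh1 * cache$fc_mask
  dz1 <- dh1 * (cache$fc_z1 > 0)
  grads$fc1_w <- t(cache$f) %*% dz1
  grads$fc1_b <- colSums(dz1)
  df <- dz1 %*% t(p$fc1_w)
  da <- t(df)
  dim(da) <- cache$pooled_dim
  for (l in 3:1) {
    dr <- maxpool_backward_cpp(da, cache[[paste0("idx", l)]],
                               cache[[paste0("rdim", l)]])
    dz <- dr * (cache[[paste0("z", l)]] > 0)
    bw <- conv2d_backward_cpp(cache[[paste0("a", l)]],
                              p[[paste0("conv", l, "_w")]], dz, cfg$stride)
    grads[[paste0("conv", l, "_w")]] <- bw$dw
    grads[[paste0("conv", l, "_b")]] <- bw$db
    da <- bw$dx
  }
  grads
}

#' Binary cross-entropy loss
#'
#' `L = -(1/N) * sum(Y * log(f) + (1 - Y) * log(1 - f))` for labels `Y`
#' in \{0, 1\} and predicted probabilities `f`.  Predictions are clipped
#' away from 0 and 1 by machine epsilon before the logs.  The loss is 0
#' exactly when every prediction equals its label.
#'
#' @param y_true Binary label vector.
#' @param y_pred Predicted probabilities, same length.
#' @return Non-negative scalar loss.
#' @export
bce_loss <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  if (!all(y_true %in% c(0, 1))) stop("y_true must be binary")
  eps <- .Machine$double.eps
  # clip each term only where its log would diverge, so a perfectly
  # confident correct prediction scores exactly zero
  f_pos <- pmax(y_pred, eps)
  f_neg <- pmin(y_pred, 1 - eps)
  -mean(y_true * log(f_pos) + (1 - y_true) * log(1 - f_neg))
}

#' Predict invasive-class scores for combined images
#'
#' @param object A trained (or untrained) `"sono_cnn"`.
#' @param images List of `(h, w, 3)` combined-image arrays, or a
#'   `(h, w, 3, n)` numeric array already scaled to `[0, 1]`.
#' @param batch_size Inference batch size (memory knob only; results are
#'   independent of batching).
#' @param ... Unused.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict.sono_cnn <- function(object, images, batch_size = 128, ...) {
  x4 <- images_to_array(images, object$config$input_size)
  n <- dim(x4)[4]
  scores <- numeric(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    xb <- x4[, , , idx, drop = FALSE]
    scores[idx] <- cnn_forward(object, xb, training = FALSE)$prob
  }
  scores
}

#' Decide the class label from a sigmoid score
#'
#' The invasive class (label 1) is declared only when the score strictly
#' exceeds 0.5; a score of exactly 0.5 falls to the non-invasive class.
#'
#' @param score Numeric vector of scores in `[0, 1]`.
#' @return Integer vector of 0/1 labels.
#' @export
decide_label <- function(score) as.integer(score > 0.5)

#' Classify combined images with a trained model
#'
#' @param model A trained `"sono_cnn"`.
#' @param images As in [predict.sono_cnn()].
#' @return A tibble with columns `score` and `label` (1 = invasive).
#' @export
classify <- function(model, images) {
  s <- predict(model, images)
  tibble::tibble(score = s, label = decide_label(s))
}

# Stack a list of integer [0,255] combined images into a (H, W, 3, N)
# double array scaled to [0, 1], validating shapes against the model.
images_to_array <- function(images, input_size = NULL) {
  if (is.array(images) && length(dim(images)) == 4) {
    return(images)
  }
  if (is.array(images) && length(dim(images)) == 3) images <- list(images)
  d <- dim(images[[1]])
  if (!is.null(input_size) && !all(d == input_size)) {
    stop("image dimensions ", paste(d, collapse = "x"),
         " do not match model input ", paste(input_size, collapse = "x"))
  }
  x4 <- array(0, dim = c(d, length(images)))
  for (i in seq_along(images)) x4[, , , i] <- images[[i]] / 255
  x4
}
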