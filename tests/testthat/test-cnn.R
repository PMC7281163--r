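test_that("weighted summation reproduces the horizontal-edge worked example", {
  filt <- rbind(c(1, 1, 1), c(0, 0, 0), c(-1, -1, -1))
  patch_edge <- rbind(c(0, 0, 0), c(0, 0, 0), c(10, 10, 10))
  patch_flat <- matrix(10, 3, 3)
  expect_equal(weighted_summation(patch_edge, filt), -30)
  expect_equal(weighted_summation(patch_flat, filt), 0)
  expect_equal(weighted_summation(matrix(0, 3, 3), filt), 0)
  expect_error(weighted_summation(matrix(0, 2, 2), filt),
               "identical dimensions")
})

test_that("binary cross-entropy matches closed forms and a per-sample oracle", {
  expect_equal(bce_loss(1, 1), 0)
  expect_equal(bce_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(bce_loss(1, 0.5), log(2))
  expect_equal(bce_loss(0, 0.5), log(2))

  set.seed(67)
  for (i in 1:10) {
    n <- sample(3:50, 1)
    y <- sample(0:1, n, replace = TRUE)
    f <- runif(n, 0.01, 0.99)
    oracle <- 0
    for (j in seq_len(n)) {
      oracle <- oracle - (if (y[j] == 1) log(f[j]) else log(1 - f[j]))
    }
    expect_equal(bce_loss(y, f), oracle / n, tolerance = 1e-12)
  }
  expect_error(bce_loss(c(1, 0), 0.5), "equal length")
})

test_that("model initialization is reproducible and sized as counted by hand", {
  cfg <- tiny_model_config(c(16, 16), conv_filters = c(4L, 8L, 16L),
                           fc_width = 8L)
  m1 <- build_model(cfg, seed = 11)
  m2 <- build_model(cfg, seed = 11)
  expect_identical(m1$params, m2$params)
  m3 <- build_model(cfg, seed = 12)
  expect_false(identical(m1$params, m3$params))

  # hand count: conv (3*3*3*4+4) + (3*3*4*8+8) + (3*3*8*16+16),
  # flat 2*2*16 = 64, fc1 64*8+8, fc2 8+1
  expect_equal(count_params(m1), 112 + 296 + 1168 + 520 + 9)
  expect_equal(m1$flat_dim, 64)
})

test_that("model outputs are valid probabilities for arbitrary input", {
  cfg <- tiny_model_config(c(16, 16))
  m <- build_model(cfg, seed = 5)
  set.seed(71)
  imgs <- replicate(4, array(sample(0:255, 16 * 16 * 3, replace = TRUE),
                             c(16, 16, 3)), simplify = FALSE)
  s <- predict(m, imgs)
  expect_length(s, 4)
  expect_true(all(s >= 0 & s <= 1))
})

test_that("too-small inputs for three pooling stages are rejected", {
  expect_error(model_config(input_size = c(4, 4, 3)), "too small")
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(input_size = c(8, 8, 3), conv_filters = c(2, 3, 4),
                      fc_width = 5, dropout_rate = 0)
  m <- build_model(cfg, seed = 7)
  set.seed(73)
  x4 <- array(runif(8 * 8 * 3 * 2), c(8, 8, 3, 2))
  y <- c(1, 0)
  fwd <- sonotype:::cnn_forward(m, x4, training = FALSE)
  gr <- sonotype:::cnn_backward(m, fwd$cache, fwd$prob, y)
  lossfn <- function(params) {
    m2 <- m
    m2$params <- params
    bce_loss(y, sonotype:::cnn_forward(m2, x4, training = FALSE)$prob)
  }
  eps <- 1e-6
  for (k in names(m$params)) {
    for (i in sample(length(m$params[[k]]), min(3, length(m$params[[k]])))) {
      pp <- m$params
      pp[[k]][i] <- pp[[k]][i] + eps
      pm <- m$params
      pm[[k]][i] <- pm[[k]][i] - eps
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_equal(gr[[k]][i], num, tolerance = 1e-4,
                   label = paste("grad", k, i))
    }
  }
})

test_that("classification threshold is strict at 0.5", {
  expect_equal(decide_label(c(0.9, 0.5, 0.3, 0.500001)), c(1L, 0L, 0L, 1L))
})

test_that("inference is deterministic and batch-invariant", {
  cfg <- tiny_model_config(c(16, 16))
  m <- build_model(cfg, seed = 3)
  set.seed(79)
  imgs <- replicate(5, array(sample(0:255, 16 * 16 * 3, replace = TRUE),
                             c(16, 16, 3)), simplify = FALSE)
  s_all <- predict(m, imgs)
  s_one <- predict(m, imgs, batch_size = 1)
  s_two <- predict(m, imgs, batch_size = 2)
  # batching only changes BLAS summation order, never the prediction
  expect_equal(s_all, s_one, tolerance = 1e-12)
  expect_equal(s_all, s_two, tolerance = 1e-12)
  expect_identical(s_all, predict(m, imgs))
})

test_that("zero epochs leaves the model at its initialization", {
  toy <- toy_separable(2)
  cfg <- tiny_model_config(c(16, 16))
  m <- build_model(cfg, seed = 9)
  t0 <- train_config("SGD", learning_rate = 0.01, batch_size = 2,
                     epochs = 0)
  m0 <- train(m, toy$images, toy$labels, t0)
  expect_identical(m0$params, m$params)
  expect_equal(nrow(m0$history), 0)
  expect_error(train(m, list(), numeric(0), t0), "empty training set")
})

test_that("each optimizer drives the loss down on a separable toy problem", {
  toy <- toy_separable(4)
  cfg <- tiny_model_config(c(16, 16), dropout_rate = 0)
  for (opt in c("SGD", "RMSprop", "Adagrad", "Adadelta", "Adam")) {
    tcfg <- train_config(opt, learning_rate = if (opt == "SGD") 0.05 else
      if (opt == "Adadelta") NULL else 0.0025,
      batch_size = 4, epochs = 8, seed = 2)
    m <- build_model(cfg, seed = 4)
    m <- train(m, toy$images, toy$labels, tcfg)
    expect_lt(m$history$train_loss[8], m$history$train_loss[1])
  }
})

test_that("training solves the bright/dark toy problem to accuracy 1", {
  toy <- toy_separable(6)
  cfg <- tiny_model_config(c(16, 16), conv_filters = c(2L, 2L, 2L),
                           fc_width = 4L, dropout_rate = 0)
  tcfg <- train_config("Adadelta", batch_size = 2, epochs = 25, seed = 2)
  m <- train(build_model(cfg, seed = 4), toy$images, toy$labels, tcfg)
  s <- predict(m, toy$images)
  expect_equal(mean(decide_label(s) == toy$labels), 1.0)
})

test_that("training is reproducible for a fixed seed", {
  toy <- toy_separable(3)
  cfg <- tiny_model_config(c(16, 16))
  tcfg <- train_config("Adam", learning_rate = 0.001, batch_size = 3,
                       epochs = 2, seed = 8)
  m1 <- train(build_model(cfg, seed = 4), toy$images, toy$labels, tcfg)
  m2 <- train(build_model(cfg, seed = 4), toy$images, toy$labels, tcfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("Adadelta's learning rate is pinned to 1", {
  expect_message(tc <- train_config("Adadelta", learning_rate = 0.1),
                 "1.00")
  expect_equal(tc$learning_rate, 1)
})

test_that("model checkpoints round-trip through JSON", {
  toy <- toy_separable(2)
  cfg <- tiny_model_config(c(16, 16))
  tcfg <- train_config("SGD", learning_rate = 0.01, batch_size = 2,
                       epochs = 1, seed = 6)
  m <- train(build_model(cfg, seed = 4), toy$images, toy$labels, tcfg)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, toy$images), predict(m, toy$images),
               tolerance = 1e-12)
})
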