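test_that("analytic gradients match finite differences", {
  spec <- cnn_spec(c(8, 8, 2), channels = c(3, 4), kernel = 3,
                   dense_width = 5)
  params <- shearwf:::cnn_init(spec, seed = 42)
  set.seed(7)
  x <- array(rnorm(8 * 8 * 2 * 6), dim = c(8, 8, 2, 6))
  y <- c(1, 0, 1, 1, 0, 0)
  g <- shearwf:::.cnn_loss_grads_cpp(params, x, y)
  check <- function(getter, setter, grad, n = 5) {
    p0 <- getter()
    idx <- sample(length(p0), min(n, length(p0)))
    for (i in idx) {
      eps <- 1e-5
      p <- p0
      p[i] <- p0[i] + eps; setter(p)
      l1 <- shearwf:::.cnn_loss_grads_cpp(params, x, y)$loss
      p[i] <- p0[i] - eps; setter(p)
      l2 <- shearwf:::.cnn_loss_grads_cpp(params, x, y)$loss
      setter(p0)
      num <- (l1 - l2) / (2 * eps)
      expect_lt(abs(num - grad[i]), 1e-5 * max(1, abs(grad[i])))
    }
  }
  for (l in 1:2) {
    check(function() params$conv[[l]]$W,
          function(p) params$conv[[l]]$W <<- p, g$conv[[l]]$W)
    check(function() params$conv[[l]]$gamma,
          function(p) params$conv[[l]]$gamma <<- p, g$conv[[l]]$gamma)
    check(function() params$conv[[l]]$beta,
          function(p) params$conv[[l]]$beta <<- p, g$conv[[l]]$beta)
  }
  check(function() params$dense1$W, function(p) params$dense1$W <<- p,
        g$dense1$W)
  check(function() params$dense2$W, function(p) params$dense2$W <<- p,
        g$dense2$W)
})

test_that("a linearly separable toy problem is learned in few epochs", {
  set.seed(1)
  n <- 200
  x <- array(rnorm(12 * 12 * 3 * n, sd = 0.1), dim = c(12, 12, 3, n))
  y <- rbinom(n, 1, 0.5)
  x[, , 1, ] <- x[, , 1, ] + rep(y * 2 - 1, each = 12 * 12)
  m <- cnn_train(x, y,
                 spec = cnn_spec(c(12, 12, 3), channels = c(4, 8),
                                 dense_width = 16),
                 config = train_config(epochs = 5, seed = 2),
                 validation = list(x = x, y = y))
  expect_gte(tail(m$history$val_accuracy, 1), 0.99)
})

test_that("zero-epoch training returns the initialized model", {
  set.seed(3)
  x <- array(rnorm(8 * 8 * 2 * 4), dim = c(8, 8, 2, 4))
  spec <- cnn_spec(c(8, 8, 2), channels = c(3, 4), dense_width = 5)
  m <- cnn_train(x, c(0, 1, 0, 1), spec = spec,
                 config = train_config(epochs = 0, seed = 9))
  expect_identical(m$params, shearwf:::cnn_init(spec, seed = 9))
  expect_null(m$history)
})

test_that("training is reproducible for a fixed seed", {
  set.seed(4)
  x <- array(rnorm(8 * 8 * 2 * 32), dim = c(8, 8, 2, 32))
  y <- rbinom(32, 1, 0.5)
  spec <- cnn_spec(c(8, 8, 2), channels = c(3, 4), dense_width = 5)
  cfg <- train_config(epochs = 2, batch_size = 8, seed = 11)
  m1 <- cnn_train(x, y, spec = spec, config = cfg)
  m2 <- cnn_train(x, y, spec = spec, config = cfg)
  expect_identical(m1$params, m2$params)
  m3 <- cnn_train(x, y, spec = spec,
                  config = train_config(epochs = 2, batch_size = 8,
                                        seed = 12))
  expect_false(identical(m3$params, m1$params))
})

test_that("a non-finite loss aborts training with the configuration", {
  set.seed(5)
  x <- array(rnorm(8 * 8 * 2 * 32), dim = c(8, 8, 2, 32))
  x[1, 1, 1, 1] <- NaN   # poisons every batch order eventually
  y <- rbinom(32, 1, 0.5)
  expect_error(
    cnn_train(x, y,
              spec = cnn_spec(c(8, 8, 2), channels = c(3, 4),
                              dense_width = 5),
              config = train_config(epochs = 1, batch_size = 32,
                                    seed = 1)),
    "training error")
})

test_that("batchnorm running statistics drive inference mode", {
  # after training, prediction must be deterministic and independent of the
  # batch composition
  set.seed(6)
  x <- array(rnorm(8 * 8 * 2 * 64), dim = c(8, 8, 2, 64))
  y <- rbinom(64, 1, 0.5)
  m <- cnn_train(x, y,
                 spec = cnn_spec(c(8, 8, 2), channels = c(3, 4),
                                 dense_width = 5),
                 config = train_config(epochs = 2, batch_size = 16,
                                       seed = 3))
  p_all <- predict(m, x)
  p_one <- vapply(1:8, function(i)
    predict(m, x[, , , c(i, i + 8), drop = FALSE])[1], numeric(1))
  expect_equal(p_one, p_all[1:8], tolerance = 1e-12)
})
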