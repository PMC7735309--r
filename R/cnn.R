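# R-side interface to the compiled patch classifier: architecture spec,
# He initialization, minibatch Adam training loop and prediction. All
# randomness (weights, shuffling) is drawn from R's RNG so a seed fixes the
# trained model exactly.

#' Specification of the patch classifier architecture
#'
#' Four convolutional layers (3x3 kernels by default), each followed by
#' batch normalization, ReLU and 2x2 max pooling, then one fully connected
#' ReLU layer and a single sigmoid output. With 21x21 input patches the
#' spatial size shrinks 21 -> 10 -> 5 -> 2 -> 1.
#'
#' @param input_dim integer \code{c(H, W, C)} of the input patches.
#' @param channels convolutional channel widths, one per layer.
#' @param kernel odd kernel size.
#' @param dense_width width of the fully connected layer.
#' @return object of class \code{cnn_spec}.
#' @export
cnn_spec <- function(input_dim, channels = c(32L, 64L, 128L, 256L),
                     kernel = 3L, dense_width = 1024L) {
  stopifnot(length(input_dim) == 3, kernel %% 2 == 1, length(channels) >= 1)
  H <- input_dim[1]
  for (l in seq_along(channels)) H <- H %/% 2L
  if (H < 1) stop("invalid spec: input too small for the pooling depth")
  structure(list(input_dim = as.integer(input_dim),
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 dense_width = as.integer(dense_width)),
            class = "cnn_spec")
}

#' @keywords internal
cnn_init <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  with_seed(seed, {
    H <- spec$input_dim[1]; W <- spec$input_dim[2]; C <- spec$input_dim[3]
    k <- spec$kernel
    conv <- vector("list", length(spec$channels))
    cin <- C
    for (l in seq_along(spec$channels)) {
      cout <- spec$channels[l]
      fan_in <- cin * k * k
      conv[[l]] <- list(
        W = matrix(stats::rnorm(cout * fan_in, sd = sqrt(2 / fan_in)),
                   cout, fan_in),
        b = matrix(0, cout, 1),
        gamma = matrix(1, cout, 1), beta = matrix(0, cout, 1),
        rmean = matrix(0, cout, 1), rvar = matrix(1, cout, 1),
        kernel = k)
      cin <- cout
      H <- H %/% 2L; W <- W %/% 2L
    }
    feat <- H * W * cin
    dw <- spec$dense_width
    params <- list(
      input_dim = spec$input_dim,
      conv = conv,
      dense1 = list(W = matrix(stats::rnorm(dw * feat, sd = sqrt(2 / feat)),
                               dw, feat),
                    b = matrix(0, dw, 1)),
      dense2 = list(W = matrix(stats::rnorm(dw, sd = sqrt(1 / dw)), 1, dw),
                    b = matrix(0, 1, 1)))
    params
  })
}

#' @keywords internal
adam_init <- function(params) {
  zeros <- function(m) matrix(0, nrow(m), ncol(m))
  list(
    conv = lapply(params$conv, function(cl) list(
      Wm = zeros(cl$W), Wv = zeros(cl$W), bm = zeros(cl$b), bv = zeros(cl$b),
      gm = zeros(cl$gamma), gv = zeros(cl$gamma),
      bem = zeros(cl$beta), bev = zeros(cl$beta))),
    dense = list(W1m = zeros(params$dense1$W), W1v = zeros(params$dense1$W),
                 b1m = zeros(params$dense1$b), b1v = zeros(params$dense1$b),
                 W2m = zeros(params$dense2$W), W2v = zeros(params$dense2$W),
                 b2m = zeros(params$dense2$b), b2v = zeros(params$dense2$b)))
}

#' Training configuration for the patch classifiers
#'
#' @param epochs passes over the training set.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param optimizer only \code{"adam"} (adaptive-moment gradient descent).
#' @param bn_momentum update rate of the batch-normalization running
#'   statistics.
#' @param seed RNG seed for initialization and shuffling.
#' @return object of class \code{train_config}.
#' @export
train_config <- function(epochs = 30L, batch_size = 64L,
                         learning_rate = 1e-3, optimizer = "adam",
                         bn_momentum = 0.1, seed = 1L) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate > 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 bn_momentum = bn_momentum, seed = as.integer(seed)),
            class = "train_config")
}

#' Train a binary patch classifier
#'
#' Minibatch Adam on the binary cross-entropy. With \code{epochs = 0} the
#' freshly initialized model is returned unchanged. Non-finite losses abort
#' with the offending configuration attached.
#'
#' @param x numeric array \code{H x W x C x N} of training patches.
#' @param y numeric vector of 0/1 labels of length N.
#' @param spec a [cnn_spec()]; defaults to the standard four-layer topology
#'   for the given input.
#' @param config a [train_config()].
#' @param validation optional \code{list(x =, y =)} held-out patches whose
#'   accuracy and F-score are reported per epoch.
#' @param verbose print per-epoch progress.
#' @return object of class \code{cnn_model}: list with \code{params},
#'   \code{spec}, \code{config} and a per-epoch \code{history} data frame.
#' @export
cnn_train <- function(x, y, spec = NULL, config = train_config(),
                      validation = NULL, verbose = FALSE) {
  d <- dim(x)
  stopifnot(length(d) == 4, length(y) == d[4])
  if (is.null(spec)) spec <- cnn_spec(d[1:3])
  params <- cnn_init(spec, seed = config$seed)
  adam <- adam_init(params)
  n <- d[4]
  history <- NULL
  t <- 0L
  if (config$epochs > 0) {
    orders <- with_seed(config$seed + 1L, lapply(seq_len(config$epochs),
                                                 function(e) sample.int(n)))
    for (epoch in seq_len(config$epochs)) {
      ord <- orders[[epoch]]
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batchnorm needs > 1 sample
        xb <- x[, , , idx, drop = FALSE]
        t <- t + 1L
        res <- .cnn_train_batch_cpp(params, adam, xb, as.numeric(y[idx]),
                                    config$learning_rate, t, 0.9, 0.999,
                                    1e-8, config$bn_momentum)
        if (!is.finite(res$loss)) {
          stop("training error: non-finite loss at epoch ", epoch,
               " (lr=", config$learning_rate,
               ", batch_size=", config$batch_size, ")")
        }
        params <- res$params
        adam <- res$adam
        losses <- c(losses, res$loss)
      }
      row <- data.frame(epoch = epoch, train_loss = mean(losses),
                        val_accuracy = NA_real_, val_fscore = NA_real_)
      if (!is.null(validation)) {
        p <- cnn_predict_params(params, validation$x)
        pred <- as.numeric(p > 0.5)
        yv <- validation$y
        row$val_accuracy <- mean(pred == yv)
        tp <- sum(pred == 1 & yv == 1)
        prec <- if (sum(pred == 1) > 0) tp / sum(pred == 1) else 0
        rec <- if (sum(yv == 1) > 0) tp / sum(yv == 1) else 0
        row$val_fscore <- if (prec + rec > 0) 2 * prec * rec / (prec + rec)
        else 0
      }
      history <- rbind(history, row)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f%s", epoch, row$train_loss,
                        if (!is.na(row$val_accuracy))
                          sprintf(", val acc %.3f", row$val_accuracy) else ""))
      }
    }
  }
  structure(list(params = params, spec = spec, config = config,
                 history = history),
            class = "cnn_model")
}

#' @keywords internal
cnn_predict_params <- function(params, x, batch = 512L) {
  d <- dim(x)
  stopifnot(length(d) == 4)
  n <- d[4]
  out <- numeric(n)
  for (start in seq(1, n, by = batch)) {
    idx <- start:min(start + batch - 1L, n)
    out[idx] <- .cnn_forward_cpp(params, x[, , , idx, drop = FALSE], FALSE)
  }
  out
}

#' Predict probabilities from a trained patch classifier
#'
#' @param object a [cnn_train()] model.
#' @param x array \code{H x W x C x N} of patches.
#' @param ... unused.
#' @return numeric vector of N probabilities.
#' @export
predict.cnn_model <- function(object, x, ...) {
  cnn_predict_params(object$params, x)
}

#' @export
print.cnn_model <- function(x, ...) {
  d <- x$spec$input_dim
  cat(sprintf(
    "Patch CNN: input %dx%dx%d, conv channels %s, dense %d, %d epochs\n",
    d[1], d[2], d[3], paste(x$spec$channels, collapse = "/"),
    x$spec$dense_width, x$config$epochs))
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf(" final train loss %.4f\n", last$train_loss))
  }
  invisible(x)
}
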