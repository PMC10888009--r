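# Neural dimensionality reduction fitted on training folds only.
#
# Two reducers are provided: an autoencoder (AE) trained by reconstruction
# loss whose bottleneck activations become the reduced features, and a
# supervised feedforward network (DNN) trained on the labels whose
# penultimate-layer activations become the reduced features. Both are small
# fully-connected networks (one hidden layer each side of the bottleneck,
# width geometric between input and bottleneck), trained full-batch with
# Adam for a fixed epoch budget, and seeded, so identical inputs give
# identical outputs.

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  layers <- vector("list", length(sizes) - 1L)
  for (l in seq_along(layers)) {
    fan_in <- sizes[l]; fan_out <- sizes[l + 1L]
    sd0 <- sqrt(2 / (fan_in + fan_out))
    layers[[l]] <- list(W = matrix(stats::rnorm(fan_in * fan_out, 0, sd0),
                                   fan_in, fan_out),
                        b = rep(0, fan_out))
  }
  layers
}

mlp_forward <- function(layers, X, acts) {
  A <- list(X)
  for (l in seq_along(layers)) {
    Zl <- sweep(A[[l]] %*% layers[[l]]$W, 2L, layers[[l]]$b, "+")
    A[[l + 1L]] <- switch(acts[l],
                          tanh = tanh(Zl),
                          sigmoid = 1 / (1 + exp(-Zl)),
                          linear = Zl)
  }
  A
}

# full-batch Adam on MSE (loss = "mse") or cross-entropy with sigmoid output
# (loss = "xent"; for both, delta at the output is simply (pred - target))
mlp_train <- function(layers, acts, X, Y, epochs, lr = 0.01, loss = "mse") {
  n <- nrow(X)
  mW <- lapply(layers, function(l) l$W * 0); vW <- mW
  mb <- lapply(layers, function(l) l$b * 0); vb <- mb
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(epochs)) {
    A <- mlp_forward(layers, X, acts)
    L <- length(layers)
    delta <- (A[[L + 1L]] - Y) / n
    if (loss == "mse" && acts[L] == "tanh")
      delta <- delta * (1 - A[[L + 1L]]^2)
    for (l in L:1) {
      gW <- crossprod(A[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- delta %*% t(layers[[l]]$W)
        if (acts[l - 1L] == "tanh") delta <- delta * (1 - A[[l]]^2)
        else if (acts[l - 1L] == "sigmoid")
          delta <- delta * A[[l]] * (1 - A[[l]])
      }
      mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
      vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
      mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
      vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
      corr1 <- 1 - b1^ep; corr2 <- 1 - b2^ep
      layers[[l]]$W <- layers[[l]]$W -
        lr * (mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps)
      layers[[l]]$b <- layers[[l]]$b -
        lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
    }
  }
  layers
}

#' Fit a dimensionality reducer on training data
#'
#' @param kind `"AE"` (autoencoder, unsupervised reconstruction) or `"DNN"`
#'   (supervised feedforward network; the penultimate layer of width `dim`
#'   provides the reduced features).
#' @param X training feature matrix (subjects x features), already
#'   standardized.
#' @param y binary 0/1 training labels (required for `"DNN"`, ignored for
#'   `"AE"`).
#' @param dim bottleneck width; defaults to 64 for >= 1000 input features and
#'   16 below.
#' @param seed integer seed (initialization is the only randomness).
#' @param epochs fixed training budget (default 200).
#' @param lr Adam learning rate.
#' @return Object of class `morphnet_reducer`.
#' @export
fit_reducer <- function(kind = c("AE", "DNN"), X, y = NULL, dim = NULL,
                        seed = 1L, epochs = 200L, lr = 0.01) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(dim)) dim <- if (p >= 1000L) 64L else 16L
  if (dim >= p) stop("reduced dimension (", dim,
                     ") must be smaller than the input width (", p, ")")
  h <- max(dim + 1L, round(sqrt(p * dim)))
  if (kind == "AE") {
    sizes <- c(p, h, dim, h, p)
    acts <- c("tanh", "linear", "tanh", "linear")
    layers <- mlp_train(mlp_init(sizes, seed), acts, X, X, epochs, lr, "mse")
    encoder_layers <- 2L
  } else {
    if (is.null(y)) stop("DNN reducer needs training labels")
    stopifnot(all(y %in% c(0, 1)))
    sizes <- c(p, h, dim, 1L)
    acts <- c("tanh", "tanh", "sigmoid")
    layers <- mlp_train(mlp_init(sizes, seed), acts, X,
                        matrix(y, ncol = 1L), epochs, lr, "xent")
    encoder_layers <- 2L
  }
  structure(list(kind = kind, layers = layers, acts = acts,
                 encoder_layers = encoder_layers, dim = dim),
            class = "morphnet_reducer")
}

#' Apply a fitted reducer to (new) features
#'
#' Deterministic: identical inputs give identical outputs.
#'
#' @param reducer a `morphnet_reducer` from [fit_reducer()].
#' @param X feature matrix on the training standardization scale.
#' @return Matrix of reduced features (subjects x `dim`).
#' @export
apply_reducer <- function(reducer, X) {
  stopifnot(inherits(reducer, "morphnet_reducer"))
  A <- mlp_forward(reducer$layers[seq_len(reducer$encoder_layers)],
                   as.matrix(X), reducer$acts[seq_len(reducer$encoder_layers)])
  A[[reducer$encoder_layers + 1L]]
}
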