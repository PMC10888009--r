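# Gaussian-process residualization of the medication confound.
#
# One GP regression per feature maps the 3-level medication code to the
# expected feature value; residuals (observed minus GP prediction) replace
# the features. Because the confound takes at most a handful of distinct
# values, the usual n x n GP algebra collapses onto the m unique inputs
# (m <= 3), which keeps fitting thousands of per-feature GPs cheap. An RBF
# kernel with unit lengthscale on the code scale is used; the signal and
# noise variances are selected per feature by maximizing the exact GP
# marginal likelihood over a fixed grid (a deterministic stand-in for
# gradient-based hyperparameter optimization).

.gp_grid <- expand.grid(s2 = c(0.05, 0.1, 0.25, 0.5, 1, 2, 5),
                        n2 = c(1e-4, 1e-3, 0.01, 0.1, 0.25, 0.5, 1, 2))

#' Fit per-feature GP confound models on training data
#'
#' @param X training feature matrix (subjects x features).
#' @param confound integer confound per training subject (medication code in
#'   1..3; any small discrete covariate works).
#' @param lengthscale RBF kernel lengthscale on the confound scale
#'   (default 1).
#' @return Object of class `gp_residualizer`.
#' @export
fit_confound_gp <- function(X, confound, lengthscale = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(confound) == n)
  confound <- as.double(confound)
  u <- sort(unique(confound))
  m <- length(u)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  if (m == 1L) {
    warning("constant confound in training data; ",
            "residualizing against the training mean only")
    return(structure(list(u = u, degenerate = TRUE, mu = mu, sdv = sdv,
                          lengthscale = lengthscale),
                     class = "gp_residualizer"))
  }
  Y <- sweep(sweep(X, 2L, mu), 2L, sdv, "/")       # standardized features
  Z <- outer(confound, u, `==`) * 1
  N <- diag(colSums(Z), m)
  ybar <- crossprod(Z, Y) / colSums(Z)             # m x p group means
  S <- N %*% ybar                                  # m x p group sums
  yty <- colSums(Y^2)
  D2 <- outer(u, u, `-`)^2
  best_ll <- rep(-Inf, p)
  best_cfg <- integer(p)
  lls <- matrix(NA_real_, nrow(.gp_grid), p)
  for (k in seq_len(nrow(.gp_grid))) {
    s2 <- .gp_grid$s2[k]; n2 <- .gp_grid$n2[k]
    B <- s2 * exp(-D2 / (2 * lengthscale^2))
    M <- solve(n2 * diag(m) + B %*% N, B)          # (sigma^2 I + B N)^-1 B
    quad <- colSums(S * (M %*% S))
    logdet <- (n - m) * log(n2) +
      determinant(n2 * diag(m) + B %*% N, logarithm = TRUE)$modulus
    lls[k, ] <- -0.5 * ((yty - quad) / n2 + logdet + n * log(2 * pi))
  }
  best_cfg <- apply(lls, 2L, which.max)
  # per-feature representer weights alpha: prediction at c* is k(c*, u) alpha
  alpha <- matrix(0, m, p)
  for (k in sort(unique(best_cfg))) {
    j <- which(best_cfg == k)
    s2 <- .gp_grid$s2[k]; n2 <- .gp_grid$n2[k]
    B <- s2 * exp(-D2 / (2 * lengthscale^2))
    alpha[, j] <- solve(N %*% B + n2 * diag(m), S[, j, drop = FALSE])
  }
  structure(list(u = u, degenerate = FALSE, mu = mu, sdv = sdv,
                 lengthscale = lengthscale, alpha = alpha,
                 s2 = .gp_grid$s2[best_cfg]),
            class = "gp_residualizer")
}

#' GP-predicted feature values at given confound levels
#'
#' @param model a `gp_residualizer`.
#' @param confound confound values (any numeric; unseen levels are handled
#'   through the kernel).
#' @return Matrix of predicted feature values on the original feature scale.
#' @export
predict_confound_gp <- function(model, confound) {
  stopifnot(inherits(model, "gp_residualizer"))
  n <- length(confound)
  p <- length(model$mu)
  if (model$degenerate) {
    pred_std <- matrix(0, n, p)
  } else {
    Kx <- exp(-outer(as.double(confound), model$u, `-`)^2 /
                (2 * model$lengthscale^2))       # n x m, unit signal variance
    pred_std <- (Kx %*% model$alpha) * rep(model$s2, each = n)
  }
  sweep(sweep(pred_std, 2L, model$sdv, "*"), 2L, model$mu, "+")
}

#' Residualize features against the fitted confound GPs
#'
#' Subtracts the GP-predicted feature values from the observed ones. The
#' model is fitted on training subjects only and applied unchanged to
#' held-out subjects.
#'
#' @param model a `gp_residualizer` from [fit_confound_gp()].
#' @param X feature matrix to residualize.
#' @param confound confound values aligned with `X`'s rows.
#' @return Residual feature matrix of the same shape as `X`.
#' @export
residualize_confound <- function(model, X, confound) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(confound))
  X - predict_confound_gp(model, confound)
}
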