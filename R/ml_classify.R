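# The three classifiers of the cascade. No SVM / random-forest / boosting
# package ships with the targeted R stack, so compact implementations are
# provided: a least-squares formulation of the RBF-kernel SVM (one linear
# solve; C = 1 by default), a random forest of variance-reduction trees with
# per-node feature subsampling, and second-order (Newton) gradient-boosted
# trees with logistic loss — all on a shared C++ exact-greedy tree learner.

rbf_kernel <- function(X1, X2, gamma) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), `+`) - 2 * tcrossprod(X1, X2)
  exp(-gamma * pmax(d2, 0))
}

median_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 60L) sample.int(n, 60L) else seq_len(n)
  d2 <- as.vector(stats::dist(X[idx, , drop = FALSE])^2)
  med <- stats::median(d2[d2 > 0])
  if (!is.finite(med) || med <= 0) med <- 1
  1 / med
}

fit_svm <- function(X, y01, C = 1, gamma = NULL) {
  y <- ifelse(y01 == 1, 1, -1)
  if (is.null(gamma)) gamma <- median_gamma(X)
  K <- rbf_kernel(X, X, gamma)
  n <- nrow(X)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / C))
  sol <- solve(A, c(0, y))
  list(kind = "svm", X = X, gamma = gamma, b = sol[1L], alpha = sol[-1L])
}

predict_svm <- function(model, X) {
  f <- rbf_kernel(X, model$X, model$gamma) %*% model$alpha + model$b
  as.integer(f > 0)
}

fit_rf <- function(X, y01, ntree = 500L, mtry = NULL, max_depth = 12L,
                   min_node = 1) {
  n <- nrow(X); p <- ncol(X)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  g <- -as.double(y01)       # leaf value = mean(y) with h = 1, lambda = 0
  h <- rep(1, n)
  trees <- lapply(seq_len(ntree), function(t) {
    rows <- sample.int(n, n, replace = TRUE) - 1L
    cpp_grow_tree(X, g, h, rows, max_depth, min_node, mtry, 0, 1e-12)
  })
  list(kind = "rf", trees = trees)
}

predict_rf <- function(model, X) {
  pr <- rowMeans(vapply(model$trees, function(tr) cpp_predict_tree(tr, X),
                        numeric(nrow(X))))
  as.integer(pr > 0.5)
}

fit_xgb <- function(X, y01, nrounds = 150L, eta = 0.1, max_depth = 3L,
                    lambda = 1, min_child_weight = 1, colsample = 0.5) {
  n <- nrow(X)
  mtry <- max(1L, ceiling(ncol(X) * colsample))
  y <- as.double(y01)
  f <- rep(0, n)                              # log-odds score
  rows <- seq_len(n) - 1L
  trees <- vector("list", nrounds)
  for (t in seq_len(nrounds)) {
    prob <- 1 / (1 + exp(-f))
    g <- prob - y
    h <- pmax(prob * (1 - prob), 1e-6)
    tr <- cpp_grow_tree(X, g, h, rows, max_depth, min_child_weight,
                        mtry, lambda, 1e-12)
    f <- f + eta * cpp_predict_tree(tr, X)
    trees[[t]] <- tr
  }
  list(kind = "xgb", trees = trees, eta = eta)
}

predict_xgb <- function(model, X) {
  f <- rep(0, nrow(X))
  for (tr in model$trees) f <- f + model$eta * cpp_predict_tree(tr, X)
  as.integer(f > 0)
}

#' Fit one of the cascade classifiers
#'
#' @param kind `"SVM"` (RBF kernel, least-squares formulation, C = 1),
#'   `"RF"` (500 trees, sqrt-p feature subsampling) or `"XGB"`
#'   (second-order gradient-boosted trees, logistic loss, depth 3,
#'   shrinkage 0.1).
#' @param X training feature matrix (standardized).
#' @param y01 binary 0/1 labels (1 = positive class).
#' @param seed integer seed for the tree learners' randomness.
#' @param ... overrides for the model hyperparameters.
#' @return Classifier object for [predict_classifier()].
#' @export
fit_classifier <- function(kind = c("SVM", "RF", "XGB"), X, y01, seed = 1L,
                           ...) {
  kind <- match.arg(kind)
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y01), all(y01 %in% c(0, 1)))
  set.seed(seed)
  switch(kind,
         SVM = fit_svm(X, y01, ...),
         RF = fit_rf(X, y01, ...),
         XGB = fit_xgb(X, y01, ...))
}

#' Predict class labels from a fitted cascade classifier
#'
#' @param model object from [fit_classifier()].
#' @param X feature matrix on the training standardization scale.
#' @return Integer vector of 0/1 predictions.
#' @export
predict_classifier <- function(model, X) {
  X <- as.matrix(X)
  switch(model$kind,
         svm = predict_svm(model, X),
         rf = predict_rf(model, X),
         xgb = predict_xgb(model, X))
}
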