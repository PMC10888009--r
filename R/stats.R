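# Group comparison statistics: two-sample permutation tests on AUC values,
# Benjamini-Hochberg FDR over nodal families, and covariate-adjusted partial
# correlation with clinical scales.

perm_diffs <- function(pooled, n1, perm_idx) {
  # mean(group1) - mean(group2) under each permuted labeling
  n <- length(pooled)
  g1 <- matrix(pooled[perm_idx[, seq_len(n1), drop = FALSE]],
               nrow = nrow(perm_idx))
  tot <- sum(pooled)
  m1 <- rowMeans(g1)
  m2 <- (tot - m1 * n1) / (n - n1)
  m1 - m2
}

#' Two-sample permutation test on a network-metric AUC
#'
#' Tests the mean difference `mean(x) - mean(y)` by randomly reassigning the
#' pooled values to two groups `B` times. The two-tailed p-value uses +1
#' smoothing: `p = (1 + #{|d_b| >= |d_obs|}) / (B + 1)`, so it never returns
#' 0 and equals 1/(B+1) at its minimum.
#'
#' @param x,y numeric AUC values for the two groups (each length >= 2).
#' @param B number of permutations (>= 100; default 10000).
#' @param seed optional seed.
#' @return List with `observed_diff`, `p_perm`, `direction` (+1/-1/0), `B`.
#' @export
permutation_test <- function(x, y, B = 10000L, seed = NULL) {
  stopifnot(length(x) >= 2L, length(y) >= 2L, B >= 100L)
  if (!is.null(seed)) set.seed(seed)
  pooled <- c(x, y)
  obs <- mean(x) - mean(y)
  if (stats::sd(pooled) == 0) {
    warning("all values identical; permutation p set to 1")
    return(list(observed_diff = 0, p_perm = 1, direction = 0, B = B))
  }
  n <- length(pooled)
  perm_idx <- t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
  d <- perm_diffs(pooled, length(x), perm_idx)
  p <- (1 + sum(abs(d) >= abs(obs))) / (B + 1)
  list(observed_diff = obs, p_perm = p, direction = sign(obs), B = B)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement:
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param q_level significance level for the discovery mask (default 0.05).
#' @return List with `q_values` (same order as input) and `significant`
#'   (logical mask `q <= q_level`).
#' @export
fdr_bh <- function(p_values, q_level = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  m <- length(p_values)
  if (m == 0L) return(list(q_values = numeric(0), significant = logical(0)))
  ord <- order(p_values)
  q_sorted <- pmin(p_values[ord] * m / seq_len(m), 1)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  list(q_values = q, significant = q <= q_level)
}

#' Partial correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after least-squares
#' projection onto an intercept plus the covariate columns; the p-value comes
#' from `t = r * sqrt(df / (1 - r^2))` with `df = n - 2 - k` covariates.
#' With no covariates this reduces exactly to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates optional numeric matrix / data.frame (e.g. age and a
#'   0/1 sex indicator), one row per observation.
#' @return List with `r`, `p`, `df`, `n`, `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  ok <- is.finite(x) & is.finite(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    storage.mode(covariates) <- "double"
    ok <- ok & apply(covariates, 1L, function(r) all(is.finite(r)))
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  k <- if (is.null(covariates)) 0L else ncol(covariates)
  if (n <= k + 2L) stop("need n > number of covariates + 2")
  if (k > 0L) {
    Z <- cbind(1, covariates[ok, , drop = FALSE])
    qr_z <- qr(Z)
    if (qr_z$rank < ncol(Z)) stop("covariate matrix is rank-deficient")
    x <- qr.resid(qr_z, x)
    y <- qr.resid(qr_z, y)
  }
  r <- stats::cor(x, y)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tval), df)
  list(r = r, p = p, df = df, n = n, n_covariates = k)
}

#' Compare network-metric AUCs between groups
#'
#' For each requested contrast, runs permutation tests on the 7 global-metric
#' AUCs (reported uncorrected) and on every node of each nodal-metric family,
#' applying BH-FDR within each contrast-by-metric nodal family.
#'
#' @param auc_list per-subject AUC summaries as returned by
#'   [cohort_metrics()]`$auc` (or [auc_summary()]).
#' @param groups factor/character of group labels aligned with `auc_list`.
#' @param contrasts list of 2-vectors `c(group1, group2)`; default all
#'   ordered pairs among BD/MDD/HC present in the data (BD vs HC, MDD vs HC,
#'   BD vs MDD).
#' @param B permutations per test (default 10000).
#' @param seed integer seed.
#' @param q_level FDR level for nodal families (default 0.05).
#' @return Tidy data.frame: one row per contrast x metric (x node for nodal
#'   families) with `observed_diff` (group1 - group2), `p_perm`, `q_fdr`
#'   (NA for global metrics) and `significant`.
#' @export
compare_groups <- function(auc_list, groups, contrasts = NULL, B = 10000L,
                           seed = 1L, q_level = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(auc_list) == length(groups))
  present <- intersect(c("BD", "MDD", "HC"), unique(groups))
  if (length(present) < 2L) stop("need at least two groups to compare")
  if (is.null(contrasts)) {
    std <- list(c("BD", "HC"), c("MDD", "HC"), c("BD", "MDD"))
    contrasts <- Filter(function(ct) all(ct %in% present), std)
  }
  set.seed(seed)
  rows <- list()
  for (ct in contrasts) {
    i1 <- which(groups == ct[1L]); i2 <- which(groups == ct[2L])
    stopifnot(length(i1) >= 2L, length(i2) >= 2L)
    n1 <- length(i1); n <- n1 + length(i2)
    idx <- c(i1, i2)
    perm_idx <- t(vapply(seq_len(B), function(b) sample.int(n), integer(n)))
    test_one <- function(vals) {
      pooled <- vals[idx]
      if (any(!is.finite(pooled))) return(c(obs = NA_real_, p = NA_real_))
      obs <- mean(pooled[seq_len(n1)]) - mean(pooled[-seq_len(n1)])
      if (stats::sd(pooled) == 0) return(c(obs = 0, p = 1))
      d <- perm_diffs(pooled, n1, perm_idx)
      c(obs = obs, p = (1 + sum(abs(d) >= abs(obs))) / (B + 1))
    }
    label <- paste(ct, collapse = " vs ")
    for (m in GLOBAL_METRIC_NAMES) {
      vals <- vapply(auc_list, function(a) a$global[[m]], numeric(1L))
      r <- test_one(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = label, family = "global", metric = m, region = NA,
        observed_diff = r[["obs"]], p_perm = r[["p"]], q_fdr = NA_real_,
        significant = r[["p"]] <= 0.05, stringsAsFactors = FALSE)
    }
    for (m in NODAL_METRIC_NAMES) {
      mat <- vapply(auc_list, function(a) a$nodal[[m]],
                    numeric(length(auc_list[[1L]]$nodal[[m]])))
      res <- apply(mat, 1L, test_one)
      adj <- if (any(!is.finite(res["p", ])))
        list(q_values = rep(NA_real_, ncol(res)),
             significant = rep(NA, ncol(res)))
      else fdr_bh(res["p", ], q_level = q_level)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = label, family = m, metric = m,
        region = rownames(mat), observed_diff = res["obs", ],
        p_perm = res["p", ], q_fdr = adj$q_values,
        significant = adj$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate nodal/global AUC metrics with clinical scores
#'
#' Partial correlations (age and 0/1 sex as covariates by default) between a
#' clinical score and each supplied metric value, BH-FDR adjusted across the
#' metrics tested.
#'
#' @param metric_values named list (or data.frame) of per-subject metric
#'   vectors.
#' @param score per-subject clinical score (NA allowed; pairwise-complete).
#' @param age,sex covariates; `sex` as M/F or 0/1.
#' @param q_level FDR level.
#' @return data.frame with `metric`, `r`, `p`, `q`, `n`.
#' @export
correlate_clinical <- function(metric_values, score, age, sex,
                               q_level = 0.05) {
  if (is.character(sex) || is.factor(sex)) sex <- as.integer(sex == "F")
  covs <- cbind(age = age, sex = sex)
  res <- lapply(names(metric_values), function(m) {
    pc <- partial_correlation(metric_values[[m]], score, covs)
    data.frame(metric = m, r = pc$r, p = pc$p, n = pc$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  adj <- fdr_bh(out$p, q_level = q_level)
  out$q <- adj$q_values
  out
}
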