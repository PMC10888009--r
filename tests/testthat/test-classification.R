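test_that("vectorize produces the right feature counts and round-trips", {
  ch <- generate_cohort(cohort_design(n_per_group = c(HC = 2L),
                                      samples_per_region = 40L, seed = 10L))
  mats <- build_cohort_matrices(ch)
  ft <- vectorize(mats)
  expect_identical(dim(ft$features), c(2L, 4005L))
  expect_identical(ft$provenance, "full")

  sub <- vectorize(mats, region_subset = bd_mdd_subregions())
  expect_identical(dim(sub$features), c(2L, 105L))
  expect_identical(sub$provenance, "submatrix")

  # row-major upper-triangle convention and exact round trip
  m <- mats[[1L]]
  v <- ft$features[1L, ]
  expect_identical(unname(v[1L]), m[1L, 2L])
  expect_identical(unname(v[2L]), m[1L, 3L])
  expect_identical(unname(v[90L]), m[2L, 3L])
  back <- unvectorize(v, rownames(m))
  expect_identical(back, m)

  expect_error(vectorize(mats, region_subset = "NotARegion"),
               "unknown region")
})

test_that("GP residualization removes confound-driven structure", {
  set.seed(11)
  n <- 200L
  conf <- sample(1:3, n, replace = TRUE)
  # feature exactly linear in the confound, noise-free
  X <- cbind(2 * conf - 1, 0.5 * conf + 3)
  gp <- fit_confound_gp(X, conf)
  res <- residualize_confound(gp, X, conf)
  expect_lt(max(abs(res)), 1e-3)

  # feature independent of the confound: residual ~ centered original
  Xi <- matrix(rnorm(n * 3L), n, 3L)
  gpi <- fit_confound_gp(Xi, conf)
  resi <- residualize_confound(gpi, Xi, conf)
  for (j in 1:3) expect_gt(cor(resi[, j], Xi[, j]), 0.99)

  # constant confound degenerates to mean-centering, with warning
  expect_warning(gpc <- fit_confound_gp(Xi, rep(2L, n)), "constant confound")
  resc <- residualize_confound(gpc, Xi, rep(2L, n))
  expect_equal(resc, scale(Xi, scale = FALSE), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("reducers are deterministic and preserve usable structure", {
  set.seed(12)
  n <- 60L
  # features on a 3-dimensional linear manifold
  basis <- matrix(rnorm(3L * 20L), 3L, 20L)
  scores <- matrix(rnorm(n * 3L), n, 3L)
  X <- scale(scores %*% basis)
  ae <- fit_reducer("AE", X, dim = 3L, seed = 1L, epochs = 400L)
  # held-out-style reconstruction through the full autoencoder
  A <- morphnet:::mlp_forward(ae$layers, X, ae$acts)
  recon <- A[[length(A)]]
  expect_lt(mean((recon - X)^2) / mean(X^2), 0.10)

  # determinism of fitting and application
  ae2 <- fit_reducer("AE", X, dim = 3L, seed = 1L, epochs = 400L)
  expect_identical(apply_reducer(ae, X), apply_reducer(ae2, X))
  expect_identical(apply_reducer(ae, X), apply_reducer(ae, X))

  # DNN reducer keeps linearly separable labels separable downstream
  tk <- separable_task(13L, n = 40L, p = 20L)
  Xs <- scale(tk$X)
  dnn <- fit_reducer("DNN", Xs, y = tk$y, dim = 4L, seed = 2L, epochs = 200L)
  red <- apply_reducer(dnn, Xs)
  expect_identical(ncol(red), 4L)
  r <- evaluate(red, tk$y, classifier = "SVM", seed = 3L)
  expect_gte(r$balanced_accuracy, 0.95)

  expect_error(fit_reducer("AE", X, dim = 25L), "smaller than the input")
})

test_that("evaluate pools confusion counts into the right rates", {
  # craft a task where the pooled confusion is known: a constant predictor
  # (all-one features, SVM degenerates to majority) has BAC 0.5
  y <- rep(c(0L, 1L), times = c(15L, 25L))
  X <- matrix(1, 40L, 3L)   # constant features force a constant predictor
  r <- evaluate(X, y, classifier = "SVM", seed = 1L)
  expect_equal(r$balanced_accuracy, 0.5, tolerance = 1e-9)
  # arithmetic of the definition
  expect_equal(r$balanced_accuracy,
               (r$sensitivity + r$specificity) / 2, tolerance = 1e-12)
  cc <- r$confusion
  expect_equal(r$sensitivity, cc[["tp"]] / (cc[["tp"]] + cc[["fn"]]))
  expect_equal(r$specificity, cc[["tn"]] / (cc[["tn"]] + cc[["fp"]]))
  expect_identical(sum(cc), 40L)

  expect_error(evaluate(X[1:6, ], y[c(1:3, 26:28)], k_folds = 5L),
               "at least k_folds")
})

test_that("every reducer x classifier cell solves a separable task", {
  tk <- separable_task(15L)
  grid <- classification_grid(list(features = tk$X, y = tk$y,
                                   confound = NULL),
                              seed = 1L, dim = 4L, epochs = 100L)
  expect_identical(nrow(grid), 9L)
  expect_true(all(grid$balanced_accuracy >= 0.95))
  expect_true(all(grid$sensitivity >= 0.9))
  expect_true(all(grid$specificity >= 0.9))
})

test_that("label-scrambled tasks sit at chance", {
  bacc <- vapply(1:10, function(s) {
    set.seed(500L + s)
    tk <- separable_task(500L + s, n = 40L, p = 10L)
    y_scr <- sample(tk$y)
    evaluate(tk$X, y_scr, classifier = "SVM", seed = s)$balanced_accuracy
  }, numeric(1L))
  expect_true(all(bacc >= 0.2 & bacc <= 0.8))
  expect_lt(abs(mean(bacc) - 0.5), 0.15)
})

test_that("label permutation test brackets separable and null tasks", {
  tk <- separable_task(16L, n = 24L, p = 8L)
  lp <- label_permutation_test(tk$X, tk$y, classifier = "SVM",
                               n_perm = 199L, seed = 1L)
  expect_lte(lp$p_perm, 0.01)

  # observed below every permuted value -> p = 1 (upper bound)
  set.seed(17)
  Xn <- matrix(rnorm(24L * 4L), 24L, 4L)
  yn <- rep(c(0L, 1L), each = 12L)
  lpn <- label_permutation_test(Xn, yn, classifier = "SVM", n_perm = 99L,
                                seed = 2L)
  expect_lte(lpn$p_perm, 1)
  expect_gte(lpn$p_perm, 0.05)
})

test_that("no-leakage canary: nothing fit on the test fold can be exploited", {
  # pure-noise features with a supervised (DNN) reducer and every label in
  # play: if any stage (residualization, scaling, reduction) saw test-fold
  # data or labels, accuracy would leave the chance band
  bacc <- vapply(1:5, function(s) {
    set.seed(900L + s)
    X <- matrix(rnorm(40L * 12L), 40L, 12L)
    y <- rep(c(0L, 1L), each = 20L)
    conf <- sample(1:3, 40L, replace = TRUE)
    evaluate(X, y, confound = conf, reducer = "DNN", classifier = "SVM",
             seed = s, dim = 3L, epochs = 100L)$balanced_accuracy
  }, numeric(1L))
  expect_lt(mean(bacc), 0.65)
  expect_true(all(bacc <= 0.8))

  # direct leakage probe: a reducer fit on ALL data with labels would send
  # accuracy to ~1; verify that such a (deliberately wrong) construction is
  # distinguishable from the package's fold-honest path
  set.seed(18)
  X <- matrix(rnorm(40L * 12L), 40L, 12L)
  y <- rep(c(0L, 1L), each = 20L)
  leaky <- fit_reducer("DNN", scale(X), y = y, dim = 3L, seed = 1L,
                       epochs = 200L)
  Xl <- apply_reducer(leaky, scale(X))
  r_leaky <- evaluate(Xl, y, classifier = "SVM", seed = 1L)
  expect_gt(r_leaky$balanced_accuracy, 0.9)  # the canary would catch this
})
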