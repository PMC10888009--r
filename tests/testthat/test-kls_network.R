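make_grid <- function(samples, n = 128L) {
  h <- stats::bw.nrd0(samples)
  seq(min(samples) - 3 * h, max(samples) + 3 * h, length.out = n)
}

test_that("estimate_density handles degenerate and large-sample inputs", {
  # all-equal samples: bandwidth fallback with warning, mode at 0.5
  x <- rep(0.5, 50L)
  grid <- seq(0.4, 0.6, length.out = 128L)
  expect_warning(p <- estimate_density(x, grid), "zero-variance")
  expect_lt(abs(p$grid[which.max(p$density)] - 0.5), 1e-3)

  # large-sample KDE approaches the analytic normal pdf
  set.seed(1)
  x <- rnorm(1e5, 0.5, 0.1)
  grid <- make_grid(x)
  p <- estimate_density(x, grid)
  truth <- dnorm(grid, 0.5, 0.1)
  expect_lt(max(abs(p$density - truth)), 0.05 * max(truth))

  expect_error(estimate_density(rnorm(10L), grid), "at least 30")
})

test_that("density renormalization holds for arbitrary inputs", {
  set.seed(2)
  for (i in 1:10) {
    x <- runif(60L, 0, i)
    grid <- make_grid(x)
    p <- estimate_density(x, grid)
    dx <- diff(grid)[1L]
    expect_equal(sum(p$density) * dx, 1, tolerance = 1e-9)
    expect_true(all(p$density > 0))
  }
})

test_that("kl_divergence has KL properties and matches the Gaussian form", {
  set.seed(3)
  x <- rnorm(5e4, 0.5, 0.1)
  y <- rnorm(5e4, 0.55, 0.1)
  grid <- make_grid(c(x, y))
  p <- estimate_density(x, grid)
  q <- estimate_density(y, grid)

  expect_identical(kl_divergence(p, p), 0)
  # closed form for equal variances: (dmu)^2 / (2 sigma^2) = 0.125
  expect_equal(kl_divergence(p, q), 0.125, tolerance = 0.0125)

  # asymmetry for unequal variances
  z <- rnorm(5e4, 0.5, 0.2)
  grid2 <- make_grid(c(x, z))
  p2 <- estimate_density(x, grid2)
  r <- estimate_density(z, grid2)
  expect_gt(abs(kl_divergence(p2, r) - kl_divergence(r, p2)), 0.05)

  expect_error(kl_divergence(p, r), "different grids")
})

test_that("kls_similarity is 1 at identity, ~0 for disjoint, Gaussian oracle", {
  set.seed(4)
  x <- rnorm(5e4, 0.5, 0.1)
  y <- rnorm(5e4, 0.55, 0.1)
  grid <- make_grid(c(x, y))
  p <- estimate_density(x, grid)
  q <- estimate_density(y, grid)
  expect_equal(kls_similarity(p, p), 1, tolerance = 1e-12)
  expect_equal(kls_similarity(p, q), kls_similarity(q, p), tolerance = 1e-12)
  # closed form exp(-(dmu)^2/sigma^2) = exp(-0.25)
  expect_equal(kls_similarity(p, q), exp(-0.25), tolerance = 0.1 * exp(-0.25))

  # (nearly) disjoint supports
  a <- rnorm(5e3, 0.1, 0.01)
  b <- rnorm(5e3, 0.9, 0.01)
  gridab <- seq(0, 1, length.out = 256L)
  expect_lt(kls_similarity(estimate_density(a, gridab),
                           estimate_density(b, gridab)), 1e-6)
})

test_that("KLS decreases monotonically with |dmu| at fixed sigma", {
  set.seed(5)
  grid <- seq(-0.2, 1.2, length.out = 256L)
  base <- estimate_density(rnorm(2e4, 0.4, 0.1), grid)
  kls <- vapply(c(0, 0.05, 0.1, 0.2, 0.3), function(d)
    kls_similarity(base, estimate_density(rnorm(2e4, 0.4 + d, 0.1), grid)),
    numeric(1L))
  expect_true(all(diff(kls) < 0))
})

test_that("similarity matrices are symmetric, unit-diagonal, order-invariant", {
  ch <- generate_cohort(cohort_design(n_per_group = c(HC = 1L),
                                      n_regions = 12L,
                                      samples_per_region = 60L, seed = 6L))
  ss <- ch$samples[[1L]]
  S <- build_similarity_matrix(ss)
  expect_identical(dim(S), c(12L, 12L))
  expect_identical(max(abs(S - t(S))), 0)
  expect_identical(unname(diag(S)), rep(1, 12L))
  expect_true(all(S > 0 & S <= 1))

  # permuting region input order yields the identical matrix
  shuffled <- ss
  set.seed(7)
  shuffled$samples <- shuffled$samples[sample(12L)]
  expect_equal(build_similarity_matrix(shuffled), S, tolerance = 0)

  # duplicating one region's samples into another forces KLS = 1
  dup <- ss
  dup$samples[[2L]] <- dup$samples[[1L]]
  S2 <- build_similarity_matrix(dup)
  expect_equal(S2[1L, 2L], 1, tolerance = 1e-9)
})
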