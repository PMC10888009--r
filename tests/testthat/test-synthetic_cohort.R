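test_that("generation is deterministic and substream-stable", {
  d <- cohort_design(n_per_group = c(HC = 3L, BD = 2L), n_regions = 10L,
                     samples_per_region = 40L, seed = 7L)
  c1 <- generate_cohort(d)
  c2 <- generate_cohort(d)
  expect_identical(c1$subjects, c2$subjects)
  expect_equal(c1$samples, c2$samples, tolerance = 0)

  # adding subjects must not perturb earlier subjects' draws
  d_big <- cohort_design(n_per_group = c(HC = 4L, BD = 2L), n_regions = 10L,
                         samples_per_region = 40L, seed = 7L)
  c3 <- generate_cohort(d_big)
  for (i in 1:3)
    expect_equal(c3$samples[[i]]$samples, c1$samples[[i]]$samples,
                 tolerance = 0)
})

test_that("null design keeps groups exchangeable", {
  # pooled per-region means from the two groups should look like one
  # distribution: two-sample KS test non-significant at alpha = 0.01 in
  # >= 95% of seeds
  n_seeds <- 100L
  reject <- logical(n_seeds)
  for (s in seq_len(n_seeds)) {
    ch <- generate_null_cohort(c(HC = 6L, MDD = 6L), seed = 1000L + s,
                               n_regions = 8L, samples_per_region = 40L)
    grp <- ch$subjects$group
    region_means <- vapply(ch$samples,
                           function(ss) mean(unlist(ss$samples)), numeric(1L))
    p <- suppressWarnings(
      stats::ks.test(region_means[grp == "HC"],
                     region_means[grp == "MDD"])$p.value)
    reject[s] <- p < 0.01
  }
  expect_gte(mean(!reject), 0.95)
})

test_that("a planted mean shift is recovered in the samples", {
  eff <- data.frame(group = "BD", region = 39L, mean_shift = 0.1,
                    sd_scale = 1)
  ch <- generate_cohort(cohort_design(n_per_group = c(HC = 30L, BD = 30L),
                                      samples_per_region = 150L,
                                      effects = eff, seed = 21L))
  grp <- ch$subjects$group
  r39 <- vapply(ch$samples, function(ss)
    mean(ss$samples[[aal90_names()[39L]]]), numeric(1L))
  diff <- mean(r39[grp == "BD"]) - mean(r39[grp == "HC"])
  # Monte-Carlo error ~ sqrt(2) * subject_sd / sqrt(30) ~ 0.007
  expect_lt(abs(diff - 0.1), 0.022)
  # an untouched region shows no such shift
  r40 <- vapply(ch$samples, function(ss)
    mean(ss$samples[[aal90_names()[40L]]]), numeric(1L))
  expect_lt(abs(mean(r40[grp == "BD"]) - mean(r40[grp == "HC"])), 0.02)
})

test_that("planted shifts surface as reduced cross-group KLS similarity", {
  eff <- data.frame(group = "BD", region = 5L, mean_shift = 0.12,
                    sd_scale = 1)
  ch <- generate_cohort(cohort_design(n_per_group = c(HC = 8L, BD = 8L),
                                      n_regions = 10L,
                                      samples_per_region = 150L,
                                      effects = eff, seed = 31L))
  mats <- build_cohort_matrices(ch)
  grp <- ch$subjects$group
  # mean similarity of the shifted region to all others, per group
  mean_sim <- vapply(mats, function(m) mean(m[5L, -5L]), numeric(1L))
  expect_lt(mean(mean_sim[grp == "BD"]), mean(mean_sim[grp == "HC"]))
})

test_that("design validation and defaults behave", {
  expect_error(generate_null_cohort(c(HC = 1L, BD = 5L), seed = 1L),
               "at least 2")
  expect_error(cohort_design(n_per_group = c(XX = 5L)), "named with groups")
  expect_error(cohort_design(effects = data.frame(group = "HC", region = 99L,
                                                  mean_shift = 1)))
  ch <- generate_null_cohort(c(HC = 3L, MDD = 3L), seed = 2L, n_regions = 5L,
                             samples_per_region = 35L)
  expect_true(all(ch$subjects$medication_code[ch$subjects$group == "HC"] == 1L))
  expect_true(all(is.na(ch$subjects$hamd[ch$subjects$group == "HC"])))
  expect_true(all(ch$subjects$hamd[ch$subjects$group == "MDD"] >= 0))
  expect_true(all(is.na(ch$subjects$ymrs[ch$subjects$group == "MDD"])))
})
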