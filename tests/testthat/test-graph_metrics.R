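test_that("sparsity thresholding keeps the right edges deterministically", {
  # round-half-up edge count on 90 nodes at S = 0.10: 400.5 -> 401
  set.seed(1)
  m <- matrix(runif(90 * 90), 90, 90); m <- (m + t(m)) / 2; diag(m) <- 1
  g <- sparsity_threshold(m, 0.10)
  expect_identical(g$retained_edges, 401L)
  expect_identical(sum(g$adjacency) / 2, 401)
  expect_identical(diag(g$adjacency), rep(0L, 90L))

  # 4-node matrix: top-2 weights are forced
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.9; w[3, 4] <- w[4, 3] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.7; w[2, 4] <- w[4, 2] <- 0.6
  g2 <- sparsity_threshold(w, 2 / 6)
  expect_identical(g2$retained_edges, 2L)
  expect_identical(g2$adjacency[1, 2], 1L)
  expect_identical(g2$adjacency[3, 4], 1L)
  expect_identical(g2$adjacency[1, 3], 0L)

  # all-equal weights: lexicographic tie-break, reproducible
  eq <- matrix(1, 5, 5); diag(eq) <- 0
  g3 <- sparsity_threshold(eq, 0.3)          # keeps 3 of 10
  g4 <- sparsity_threshold(eq, 0.3)
  expect_identical(g3$adjacency, g4$adjacency)
  expect_identical(which(g3$adjacency[1, ] == 1L), 2:4)  # (1,2),(1,3),(1,4)

  expect_error(sparsity_threshold(m, 0), "between 0 and 1")
  expect_error(sparsity_threshold(m, 1.2), "between 0 and 1")
})

test_that("global metrics match closed forms on canonical graphs", {
  # complete graph K90
  k90 <- matrix(1L, 90, 90); diag(k90) <- 0L
  gm <- global_metrics(k90, n_random_refs = 0L)
  expect_equal(gm$Cp, 1)
  expect_equal(gm$Lp, 1)
  expect_equal(gm$Eglob, 1)
  expect_equal(gm$Eloc, 1)

  # 5-cycle: Cp = 0, Lp = 1.5, Eglob = 0.75 (brute-force enumerable)
  c5 <- matrix(0L, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; c5[i, j] <- c5[j, i] <- 1L }
  gm5 <- global_metrics(c5, n_random_refs = 0L)
  expect_equal(gm5$Cp, 0)
  expect_equal(gm5$Lp, 1.5)
  expect_equal(gm5$Eglob, 0.75)

  expect_error(global_metrics(matrix(0L, 4, 4)), "no edges")
})

test_that("nodal metrics match hand enumeration on star and path", {
  # star with 4 leaves: center degree 4, center betweenness 6 (all 6 leaf
  # pairs), leaves 0
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1L
  nm <- nodal_metrics(star)
  expect_identical(nm$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(nm$betweenness, c(6, 0, 0, 0, 0))

  # path a-b-c: betweenness(b) = 1, nodal efficiency(b) = 1
  path <- matrix(0L, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- 1L
  nmp <- nodal_metrics(path)
  expect_equal(nmp$betweenness, c(0, 1, 0))
  expect_equal(nmp$nodal_efficiency[2L], 1)
  expect_equal(nmp$nodal_efficiency[1L], (1 + 0.5) / 2)

  # complete graph: betweenness 0, nodal efficiency 1 everywhere
  k6 <- matrix(1L, 6, 6); diag(k6) <- 0L
  nmk <- nodal_metrics(k6)
  expect_equal(nmk$betweenness, rep(0, 6))
  expect_equal(nmk$nodal_efficiency, rep(1, 6))
})

test_that("metrics agree with the igraph oracle on random graphs", {
  for (s in 1:12) {
    adj <- random_adj(30L, p_edge = runif(1, 0.1, 0.5), seed = 600L + s)
    if (sum(adj) == 0) next
    ig <- adj_to_igraph(adj)
    gm <- global_metrics(adj, n_random_refs = 0L)
    nm <- nodal_metrics(adj)
    expect_equal(gm$Cp,
                 igraph::transitivity(ig, type = "localaverage",
                                      isolates = "zero"),
                 tolerance = 1e-9)
    expect_equal(gm$Lp, igraph::mean_distance(ig), tolerance = 1e-9)
    expect_equal(gm$Eglob, igraph::global_efficiency(ig), tolerance = 1e-9)
    expect_equal(nm$degree, unname(igraph::degree(ig)))
    expect_equal(nm$betweenness, unname(igraph::betweenness(ig)),
                 tolerance = 1e-9)
    D <- igraph::distances(ig)
    inv <- 1 / D
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    expect_equal(nm$nodal_efficiency, unname(rowSums(inv) / 29),
                 tolerance = 1e-9)
    # local efficiency: igraph-built neighbor subgraphs, global efficiency each
    eloc_oracle <- mean(vapply(seq_len(30L), function(i) {
      nb <- which(adj[i, ] == 1L)
      if (length(nb) < 2L) return(0)
      igraph::global_efficiency(adj_to_igraph(adj[nb, nb, drop = FALSE]))
    }, numeric(1L)))
    expect_equal(gm$Eloc, eloc_oracle, tolerance = 1e-9)
  }
})

test_that("rewired references preserve degrees; sigma ~ 1 on its own ensemble", {
  adj <- random_adj(40L, 0.2, seed = 77L)
  refs <- random_references(adj, n_refs = 20L, seed = 1L)
  for (r in refs) {
    expect_identical(colSums(r), colSums(adj))
    expect_identical(max(abs(r - t(r))), 0L)
    expect_identical(diag(r), rep(0L, 40L))
  }
  # references differ from the original (rewiring actually happened)
  expect_gt(sum(vapply(refs, function(r) sum(abs(r - adj)), numeric(1L))), 0)

  # an already-random graph scored against its own ensemble: sigma ~ 1
  # (denser graph: single-draw clustering fluctuates less around the
  # ensemble mean)
  adj2 <- random_adj(60L, 0.3, seed = 78L)
  gm <- global_metrics(adj2, n_random_refs = 100L, seed = 2L)
  expect_lt(abs(gm$sigma - 1), 0.1)
})

test_that("a lattice with shortcuts is small-world (sigma > 1)", {
  # ring lattice, 60 nodes, 4 neighbors each side, plus a few shortcuts
  n <- 60L
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in 1:4) {
    j <- (i + d - 1L) %% n + 1L
    adj[i, j] <- adj[j, i] <- 1L
  }
  set.seed(3)
  for (k in 1:6) {
    ij <- sample.int(n, 2L)
    adj[ij[1L], ij[2L]] <- adj[ij[2L], ij[1L]] <- 1L
  }
  gm <- global_metrics(adj, n_random_refs = 50L, seed = 4L)
  expect_gt(gm$sigma, 1)
})

test_that("metric curves are monotone where edge addition forces it", {
  set.seed(8)
  m <- matrix(runif(40 * 40), 40, 40); m <- (m + t(m)) / 2; diag(m) <- 1
  mc <- metric_curves(m, thresholds = seq(0.10, 0.34, by = 0.04),
                      n_random_refs = 0L)
  expect_true(all(diff(mc$global["Eglob", ]) >= 0))
  expect_true(all(apply(mc$nodal$degree, 1L, function(v) all(diff(v) >= 0))))
  # default sweep has 25 thresholds
  expect_length(default_sparsity_sweep(), 25L)
  # degree sum = 2 * edges at every threshold
  for (t in seq_along(mc$thresholds)) {
    g <- sparsity_threshold(m, mc$thresholds[t])
    expect_identical(sum(mc$nodal$degree[, t]), as.double(2L * g$retained_edges))
  }
})

test_that("curve AUC matches the summation oracle and closed forms", {
  th <- default_sparsity_sweep()
  expect_equal(curve_auc(rep(2, 25L), th), 0.48, tolerance = 1e-12)
  lin <- seq(0, 1, length.out = 25L)
  expect_equal(curve_auc(lin, th), 0.12, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:5) {
    v <- rnorm(25L)
    expect_equal(curve_auc(v, th), bf_trapz(v, th), tolerance = 1e-12)
  }
  # matrix form consistent with per-row scalar form
  V <- matrix(rnorm(3 * 25), 3, 25)
  expect_equal(curve_auc(V, th),
               apply(V, 1L, bf_trapz, x = th), tolerance = 1e-12)
})
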