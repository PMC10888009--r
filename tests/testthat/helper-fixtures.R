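# Shared fixtures (memoized: the 20-subject default cohort and its metrics
# are expensive and reused across acceptance criteria) and small independent
# oracles used to cross-check package computations.

.fixtures <- new.env()

memo <- function(key, compute) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- compute()
  .fixtures[[key]]
}

# the default synthetic cohort of the acceptance criteria: 20 subjects,
# full 90-region parcellation, fixed seed
cohort20 <- function() memo("cohort20", function()
  generate_cohort(cohort_design(n_per_group = c(HC = 10L, BD = 10L),
                                seed = 1L)))

cohort20_matrices <- function() memo("cohort20_matrices", function()
  build_cohort_matrices(cohort20()))

cohort20_metrics <- function() memo("cohort20_metrics", function()
  cohort_metrics(cohort20_matrices(), n_random_refs = 100L, seed = 1L))

# linearly separable binary task: per-feature class overlap is negligible
separable_task <- function(seed, n = 40L, p = 30L, shift = 3, sd = 0.5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(stats::rnorm(n * p, sd = sd), n, p) + outer(y, rep(shift, p))
  list(X = X, y = y)
}

# --- independent oracles -------------------------------------------------

# trapezoidal AUC by explicit summation
bf_trapz <- function(v, x) {
  s <- 0
  for (i in seq_len(length(x) - 1L))
    s <- s + (v[i] + v[i + 1L]) * (x[i + 1L] - x[i]) / 2
  s
}

# Benjamini-Hochberg by direct definition
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p[ord][i:m] * m / (i:m)
    q[ord[i]] <- min(min(cand), 1)
  }
  q
}

# all-pairs shortest path lengths by plain matrix-power BFS
bf_dist <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) == 1
  step <- adj > 0
  cur <- reach
  for (d in seq_len(n)) {
    cur <- (cur %*% step) > 0
    newly <- cur & !reach
    if (!any(newly)) break
    D[newly] <- d
    reach <- reach | newly
  }
  D
}

# random symmetric adjacency matrix with given edge probability
random_adj <- function(n, p_edge, seed) {
  set.seed(seed)
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(stats::runif(n * (n - 1) / 2) < p_edge)
  a + t(a)
}

adj_to_igraph <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}
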