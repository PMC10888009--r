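# Sparsity thresholding and graph-theory metrics over the threshold sweep.
#
# Matrices are binarized at each sparsity level S (fraction of the N(N-1)/2
# possible edges retained), and each binary graph is summarized by the
# small-world parameters (Cp, Lp, gamma, lambda, sigma), network efficiency
# (Eglob, Eloc) and nodal centralities (degree, nodal efficiency,
# betweenness). Metric-versus-sparsity curves are reduced to scalars by
# trapezoidal area under the curve (AUC).

GLOBAL_METRIC_NAMES <- c("Cp", "Lp", "gamma", "lambda", "sigma",
                         "Eglob", "Eloc")
NODAL_METRIC_NAMES <- c("degree", "nodal_efficiency", "betweenness")

#' Default sparsity sweep: 0.10 to 0.34 in steps of 0.01
#' @return Numeric vector of 25 thresholds.
#' @export
default_sparsity_sweep <- function() seq(0.10, 0.34, by = 0.01)

round_half_up <- function(x) floor(x + 0.5)

#' Binarize a similarity matrix at a sparsity threshold
#'
#' Keeps the `round_half_up(S * N(N-1)/2)` largest off-diagonal weights as
#' edges of an undirected simple graph. Ties are broken by weight descending,
#' then (row, column) lexicographic ascending, so the edge set is
#' deterministic.
#'
#' @param matrix square symmetric numeric matrix (diagonal ignored).
#' @param S sparsity in (0, 1).
#' @return Object of class `thresholded_graph` with fields `adjacency`
#'   (0/1 integer matrix), `sparsity`, `retained_edges`, `labels`.
#' @export
sparsity_threshold <- function(matrix, S) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (!is.numeric(S) || length(S) != 1L || S <= 0 || S >= 1)
    stop("sparsity S must lie strictly between 0 and 1")
  n <- nrow(matrix)
  n_possible <- n * (n - 1) / 2
  m <- as.integer(round_half_up(S * n_possible))
  ut <- which(upper.tri(matrix), arr.ind = TRUE)
  w <- matrix[ut]
  ord <- order(-w, ut[, 1L], ut[, 2L])
  keep <- ord[seq_len(min(m, length(ord)))]
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(matrix)
  structure(list(adjacency = adj, sparsity = S, retained_edges = m,
                 labels = rownames(matrix)),
            class = "thresholded_graph")
}

#' @export
print.thresholded_graph <- function(x, ...) {
  cat("<thresholded_graph>", nrow(x$adjacency), "nodes,", x$retained_edges,
      "edges (S =", x$sparsity, ")\n")
  invisible(x)
}

as_adjacency <- function(g) {
  if (inherits(g, "thresholded_graph")) g$adjacency else {
    stopifnot(is.matrix(g))
    a <- (g != 0) * 1L
    diag(a) <- 0L
    a
  }
}

#' Degree-preserving random reference graphs
#'
#' Maslov-Sneppen double-edge-swap rewiring; each reference starts from the
#' observed graph and performs `swap_factor * |E|` swap attempts. Driven by
#' R's RNG, so wrap in `set.seed()` (or pass `seed`) for reproducibility.
#'
#' @param g `thresholded_graph` or adjacency matrix.
#' @param n_refs number of references (default 100).
#' @param swap_factor attempts per edge (default 10).
#' @param seed optional integer seed.
#' @return List of adjacency matrices with the exact degree sequence of `g`.
#' @export
random_references <- function(g, n_refs = 100L, swap_factor = 10L,
                              seed = NULL) {
  adj <- as_adjacency(g)
  if (!is.null(seed)) set.seed(seed)
  m <- sum(adj) / 2
  attempts <- as.integer(swap_factor * m)
  deg <- colSums(adj)
  lapply(seq_len(n_refs), function(i) {
    ref <- cpp_rewire(adj, attempts)
    stopifnot(identical(colSums(ref), deg))  # degree sequence preserved
    ref
  })
}

#' Global network metrics of a binary graph
#'
#' Computes Cp (mean local clustering; nodes of degree < 2 contribute 0), Lp
#' (mean shortest path over connected ordered pairs), Eglob, Eloc, and the
#' normalized small-world parameters gamma = Cp / <Cp_rand>, lambda =
#' Lp / <Lp_rand>, sigma = gamma / lambda, where the reference averages come
#' from degree-preserving rewired graphs.
#'
#' @param g `thresholded_graph` or adjacency matrix with at least one edge.
#' @param n_random_refs number of rewired references (default 100).
#' @param seed integer seed for the reference ensemble.
#' @return Named list with Cp, Lp, gamma, lambda, sigma, Eglob, Eloc.
#' @export
global_metrics <- function(g, n_random_refs = 100L, seed = NULL) {
  adj <- as_adjacency(g)
  if (sum(adj) == 0) stop("graph has no edges")
  cl <- cpp_cp_lp(adj)
  eff <- cpp_efficiency(adj)
  eloc <- cpp_local_efficiency(adj)
  if (n_random_refs > 0L) {
    refs <- random_references(adj, n_refs = n_random_refs, seed = seed)
    ref_cl <- vapply(refs, cpp_cp_lp, numeric(2L))
    gamma <- cl[1L] / mean(ref_cl[1L, ])
    lambda <- cl[2L] / mean(ref_cl[2L, ])
  } else {
    gamma <- lambda <- NA_real_  # normalized metrics need the null ensemble
  }
  list(Cp = cl[1L], Lp = cl[2L], gamma = gamma, lambda = lambda,
       sigma = gamma / lambda, Eglob = eff$eglob, Eloc = eloc)
}

#' Nodal metrics of a binary graph
#'
#' Degree (row sums), nodal efficiency (mean inverse distance to all other
#' nodes), and unnormalized Brandes betweenness (each unordered pair counted
#' once, even splitting over equal-length geodesics).
#'
#' @param g `thresholded_graph` or adjacency matrix.
#' @return data.frame with columns `region`, `degree`, `nodal_efficiency`,
#'   `betweenness`.
#' @export
nodal_metrics <- function(g) {
  adj <- as_adjacency(g)
  labels <- rownames(adj)
  if (is.null(labels)) labels <- paste0("node", seq_len(nrow(adj)))
  eff <- cpp_efficiency(adj)
  data.frame(region = labels,
             degree = as.integer(colSums(adj)),
             nodal_efficiency = eff$nodal_efficiency,
             betweenness = cpp_betweenness(adj),
             stringsAsFactors = FALSE)
}

#' Metric curves across the sparsity sweep
#'
#' Thresholds the matrix at every sparsity in the sweep and evaluates all
#' global and nodal metrics.
#'
#' @param matrix square symmetric similarity matrix.
#' @param thresholds sparsity sweep (default `default_sparsity_sweep()`).
#' @param n_random_refs rewired references per threshold for gamma/lambda/
#'   sigma (default 100; 0 skips the null ensemble and reports NA for the
#'   normalized metrics).
#' @param seed integer seed for the reference ensembles.
#' @return Object of class `metric_curves`: `thresholds`, `global` (matrix
#'   metrics x thresholds), `nodal` (list of node x threshold matrices).
#' @export
metric_curves <- function(matrix, thresholds = default_sparsity_sweep(),
                          n_random_refs = 100L, seed = NULL) {
  stopifnot(length(thresholds) >= 1L, !is.unsorted(thresholds, strictly = TRUE))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(matrix)
  labels <- rownames(matrix)
  if (is.null(labels)) labels <- paste0("node", seq_len(n))
  glob <- matrix(NA_real_, length(GLOBAL_METRIC_NAMES), length(thresholds),
                 dimnames = list(GLOBAL_METRIC_NAMES, NULL))
  nodal <- lapply(NODAL_METRIC_NAMES, function(m)
    matrix(NA_real_, n, length(thresholds), dimnames = list(labels, NULL)))
  names(nodal) <- NODAL_METRIC_NAMES
  for (t in seq_along(thresholds)) {
    g <- sparsity_threshold(matrix, thresholds[t])
    gm <- global_metrics(g, n_random_refs = n_random_refs, seed = NULL)
    glob[, t] <- unlist(gm[GLOBAL_METRIC_NAMES])
    nm <- nodal_metrics(g)
    nodal$degree[, t] <- nm$degree
    nodal$nodal_efficiency[, t] <- nm$nodal_efficiency
    nodal$betweenness[, t] <- nm$betweenness
  }
  structure(list(thresholds = thresholds, global = glob, nodal = nodal),
            class = "metric_curves")
}

#' @export
print.metric_curves <- function(x, ...) {
  cat("<metric_curves>", length(x$thresholds), "thresholds [",
      min(x$thresholds), ",", max(x$thresholds), "],",
      nrow(x$nodal$degree), "nodes\n")
  invisible(x)
}

#' Trapezoidal area under a metric curve
#'
#' @param values metric values (vector, or matrix with one row per node and
#'   one column per threshold).
#' @param thresholds the sparsity values the curve was evaluated at.
#' @return Scalar AUC for a vector input; per-node vector for a matrix.
#' @export
curve_auc <- function(values, thresholds) {
  stopifnot(length(thresholds) >= 2L)
  dt <- diff(thresholds)
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(thresholds))
    k <- ncol(values)
    as.vector((values[, -1L, drop = FALSE] +
                 values[, -k, drop = FALSE]) %*% dt / 2)
  } else {
    stopifnot(length(values) == length(thresholds))
    sum((values[-1L] + values[-length(values)]) * dt / 2)
  }
}

#' AUC summary of a set of metric curves
#'
#' @param curves a `metric_curves` object.
#' @return List with `global` (named numeric: one AUC per global metric) and
#'   `nodal` (list of named per-node AUC vectors per nodal metric).
#' @export
auc_summary <- function(curves) {
  stopifnot(inherits(curves, "metric_curves"))
  th <- curves$thresholds
  global <- vapply(rownames(curves$global),
                   function(m) curve_auc(curves$global[m, ], th), numeric(1L))
  nodal <- lapply(curves$nodal, function(v)
    stats::setNames(curve_auc(v, th), rownames(v)))
  list(global = global, nodal = nodal)
}

#' Metric curves and AUCs for a whole cohort
#'
#' Runs [metric_curves()] on each subject's similarity matrix with a
#' per-subject seed derived from `seed`, and collects AUC summaries.
#'
#' @param matrices named list of similarity matrices.
#' @param thresholds sparsity sweep.
#' @param n_random_refs rewired references per threshold.
#' @param seed base seed; subject i uses `seed + i`.
#' @return List with `curves` (per subject) and `auc` (per subject).
#' @export
cohort_metrics <- function(matrices, thresholds = default_sparsity_sweep(),
                           n_random_refs = 100L, seed = 1L) {
  curves <- vector("list", length(matrices))
  names(curves) <- names(matrices)
  for (i in seq_along(matrices))
    curves[[i]] <- metric_curves(matrices[[i]], thresholds = thresholds,
                                 n_random_refs = n_random_refs,
                                 seed = seed + i)
  list(curves = curves, auc = lapply(curves, auc_summary))
}
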