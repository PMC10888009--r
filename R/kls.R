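# KLS morphological connectome construction.
#
# Each region's gray-matter intensity samples are turned into a probability
# density estimated by Gaussian-kernel KDE on a grid shared across all the
# subject's regions; pairwise similarity is the exponentiated negative
# symmetrized Kullback-Leibler divergence, KLS = exp(-[KL(P||Q) + KL(Q||P)]),
# which is 1 for identical distributions and tends to 0 for disjoint ones.

#' Shared KDE evaluation grid for one subject
#'
#' Equispaced grid spanning the subject's pooled sample range extended by
#' three pooled-sample bandwidths each side, so every region's kernel mass is
#' captured on a common support.
#'
#' @param sample_set an `roi_sample_set`.
#' @param n_points number of grid points (default 128).
#' @return Strictly increasing numeric vector of length `n_points`.
#' @export
shared_grid <- function(sample_set, n_points = 128L) {
  pooled <- unlist(sample_set$samples, use.names = FALSE)
  h <- tryCatch(stats::bw.nrd0(pooled), error = function(e) 1e-3)
  if (!is.finite(h) || h <= 0) h <- 1e-3
  seq(min(pooled) - 3 * h, max(pooled) + 3 * h, length.out = n_points)
}

#' Gaussian-kernel density profile on a fixed grid
#'
#' Evaluates a Gaussian KDE on the supplied equispaced grid, floors the
#' density at `floor` (so overlapping-support divergences stay finite) and
#' renormalizes to integrate to 1.
#'
#' @param samples numeric vector, at least 30 finite values.
#' @param grid equispaced evaluation grid.
#' @param bandwidth kernel bandwidth; default Silverman's rule-of-thumb
#'   (`stats::bw.nrd0`). Zero-variance samples fall back to 1e-3 with a
#'   warning.
#' @param floor density floor before renormalization (default 1e-10).
#' @return An object of class `density_profile` with fields `grid` and
#'   `density` (integrates to 1).
#' @export
estimate_density <- function(samples, grid, bandwidth = NULL, floor = 1e-10) {
  samples <- as.double(samples)
  if (length(samples) < 30L)
    stop("need at least 30 samples for density estimation, got ",
         length(samples))
  if (!all(is.finite(samples))) stop("samples must be finite")
  dx <- diff(grid)
  if (any(dx <= 0) || max(abs(dx - dx[1L])) > 1e-9 * dx[1L])
    stop("grid must be strictly increasing and equispaced")
  if (is.null(bandwidth)) {
    if (stats::sd(samples) == 0) {
      warning("zero-variance samples; falling back to bandwidth = 1e-3")
      bandwidth <- 1e-3
    } else {
      bandwidth <- stats::bw.nrd0(samples)
      if (!is.finite(bandwidth) || bandwidth <= 0) bandwidth <- 1e-3
    }
  }
  n <- length(grid)
  dens <- stats::density(samples, bw = bandwidth, kernel = "gaussian",
                         from = grid[1L], to = grid[n], n = n)$y
  dens <- pmax(dens, floor)
  dens <- dens / (sum(dens) * dx[1L])
  structure(list(grid = grid, density = dens), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("<density_profile>", length(x$grid), "points on [",
      signif(x$grid[1L], 4), ",", signif(x$grid[length(x$grid)], 4), "]\n")
  invisible(x)
}

profile_masses <- function(p) {
  dx <- p$grid[2L] - p$grid[1L]
  m <- p$density * dx
  m / sum(m)
}

check_same_grid <- function(p, q) {
  if (length(p$grid) != length(q$grid) ||
      max(abs(p$grid - q$grid)) > 1e-12 * max(1, abs(p$grid[1L])))
    stop("density profiles are on different grids")
}

#' Discrete Kullback-Leibler divergence between two profiles
#'
#' KL(P||Q) over bin masses on the shared grid; non-negative, zero iff the
#' profiles coincide, and asymmetric in general.
#'
#' @param p,q `density_profile` objects on the same grid.
#' @return Non-negative scalar.
#' @export
kl_divergence <- function(p, q) {
  check_same_grid(p, q)
  pm <- profile_masses(p)
  qm <- profile_masses(q)
  max(sum(pm * (log(pm) - log(qm))), 0)
}

#' KLS similarity between two density profiles
#'
#' `exp(-(KL(P||Q) + KL(Q||P)))`: symmetric, in (0, 1], equal to 1 iff the
#' profiles are identical.
#'
#' @param p,q `density_profile` objects on the same grid.
#' @return Scalar in (0, 1].
#' @export
kls_similarity <- function(p, q) {
  min(exp(-(kl_divergence(p, q) + kl_divergence(q, p))), 1)
}

#' Build a subject's KLS similarity matrix
#'
#' Estimates one density per region on a subject-shared grid and fills all
#' unordered region pairs with their KLS similarity; the diagonal is exactly
#' 1. Regions carrying AAL names are canonicalized first, so the output is
#' order-invariant.
#'
#' @param sample_set an `roi_sample_set`.
#' @param grid_points grid resolution (default 128).
#' @param floor density floor (default 1e-10).
#' @return Symmetric labeled matrix (regions x regions) with unit diagonal.
#' @export
build_similarity_matrix <- function(sample_set, grid_points = 128L,
                                    floor = 1e-10) {
  if (all(region_names(sample_set) %in% aal90_names()))
    sample_set <- canonicalize_regions(sample_set)
  grid <- shared_grid(sample_set, grid_points)
  labels <- region_names(sample_set)
  n <- length(labels)
  M <- matrix(0, n, length(grid))
  for (i in seq_len(n))
    M[i, ] <- profile_masses(estimate_density(sample_set$samples[[i]], grid,
                                              floor = floor))
  logM <- log(M)
  self <- rowSums(M * logM)
  # KL[i, j] = sum_k M[i,k] (log M[i,k] - log M[j,k])
  KL <- pmax(self - M %*% t(logM), 0)
  S <- exp(-(KL + t(KL)))
  S <- pmin((S + t(S)) / 2, 1)   # exact symmetry against rounding
  diag(S) <- 1
  dimnames(S) <- list(labels, labels)
  S
}

#' Build similarity matrices for every subject of a cohort
#'
#' @param ch a `morphnet_cohort`.
#' @param grid_points,floor passed to [build_similarity_matrix()].
#' @return Named list of similarity matrices, one per subject.
#' @export
build_cohort_matrices <- function(ch, grid_points = 128L, floor = 1e-10) {
  lapply(ch$samples, build_similarity_matrix, grid_points = grid_points,
         floor = floor)
}
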