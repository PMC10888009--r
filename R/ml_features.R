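# Feature extraction from connectome matrices: the strict upper triangle in
# row-major order, optionally restricted to a region subset (the 15-region
# fronto-limbic/prefrontal subset that separates BD from MDD).

#' The 15-region subset distinguishing BD from MDD
#'
#' Regions whose nodal centralities differ between the BD and MDD groups;
#' used for the 15x15 submatrix feature set (105 features).
#'
#' @return Character vector of 15 canonical AAL-90 names.
#' @export
bd_mdd_subregions <- function() {
  c("Frontal_Sup_L", "Frontal_Sup_R", "Frontal_Sup_Orb_L",
    "Frontal_Mid_L", "Frontal_Mid_R", "Frontal_Inf_Oper_R",
    "Supp_Motor_Area_L", "Supp_Motor_Area_R",
    "Frontal_Sup_Medial_L", "Frontal_Sup_Medial_R",
    "Hippocampus_L", "Parietal_Sup_L", "Caudate_R", "Thalamus_L",
    "Temporal_Pole_Sup_R")
}

upper_tri_rowmajor <- function(m) t(m)[lower.tri(m)]

upper_tri_names <- function(labels) {
  n <- length(labels)
  idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  paste(labels[idx[, 2L]], labels[idx[, 1L]], sep = "|")
}

#' Vectorize similarity matrices into a feature table
#'
#' One row per subject: the strict upper triangle (diagonal excluded) of the
#' (optionally sub-setted) matrix in row-major order — 4005 features for
#' 90 regions, 105 for the 15-region subset.
#'
#' @param matrices named list of labeled symmetric matrices (shared labels).
#' @param region_subset optional character vector of region names to restrict
#'   to (order follows the matrix, not the subset).
#' @return List of class `feature_table`: `features` (subjects x features
#'   matrix), `subject_ids`, `provenance` (`"full"` or `"submatrix"`).
#' @export
vectorize <- function(matrices, region_subset = NULL) {
  stopifnot(length(matrices) >= 1L)
  labels <- rownames(matrices[[1L]])
  if (is.null(labels)) stop("matrices must carry region labels")
  if (!is.null(region_subset)) {
    unknown <- setdiff(region_subset, labels)
    if (length(unknown))
      stop("unknown region name(s): ", paste(unknown, collapse = ", "))
    keep <- labels[labels %in% region_subset]
  } else keep <- labels
  feat <- t(vapply(matrices, function(m) {
    stopifnot(identical(rownames(m), labels))
    upper_tri_rowmajor(m[keep, keep, drop = FALSE])
  }, numeric(length(keep) * (length(keep) - 1L) / 2L)))
  colnames(feat) <- upper_tri_names(keep)
  structure(list(features = feat,
                 subject_ids = names(matrices),
                 region_labels = keep,
                 provenance = if (is.null(region_subset)) "full" else "submatrix"),
            class = "feature_table")
}

#' Rebuild a symmetric matrix from an upper-triangle feature vector
#'
#' Inverse of one row of [vectorize()]; the diagonal is set to 1 (the KLS
#' self-similarity).
#'
#' @param v feature vector of length `n(n-1)/2`.
#' @param labels the n region labels.
#' @return Symmetric labeled matrix with unit diagonal.
#' @export
unvectorize <- function(v, labels) {
  n <- length(labels)
  stopifnot(length(v) == n * (n - 1L) / 2L)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v          # row-major upper triangle = column-major lower
  m <- t(m)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  m
}
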