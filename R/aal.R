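#' The AAL-90 parcellation table
#'
#' Returns the canonical 90-region non-cerebellar automated anatomical
#' labeling (AAL) table in standard numbering (odd indices = left hemisphere,
#' even = right). All connectome matrices in the package are ordered by this
#' table, which makes them comparable across subjects.
#'
#' @return A data.frame with columns `index` (1..90) and `name`.
#' @export
#' @examples
#' head(aal90_regions())
aal90_regions <- function() {
  if (is.null(.morphnet_env$aal90)) {
    path <- system.file("extdata", "aal90.csv", package = "morphnet", mustWork = TRUE)
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(nrow(tab) == 90L, identical(tab$index, 1:90))
    .morphnet_env$aal90 <- tab
  }
  .morphnet_env$aal90
}

.morphnet_env <- new.env(parent = emptyenv())

#' Canonical AAL-90 region names
#'
#' @return Character vector of 90 region names in canonical order.
#' @export
aal90_names <- function() aal90_regions()$name

#' Map region labels to canonical AAL-90 positions
#'
#' Case-sensitive exact matching against the shipped AAL-90 table. Used by
#' every reader to canonicalize region order; idempotent and independent of
#' the input order.
#'
#' @param labels character vector of region labels.
#' @return Integer vector of canonical positions (1..90).
#' @export
aal90_match <- function(labels) {
  idx <- match(labels, aal90_names())
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown AAL-90 region label(s): ", paste(bad, collapse = ", "))
  }
  idx
}
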