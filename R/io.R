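#' @include aal.R
NULL

.GROUPS <- c("HC", "MDD", "BD")

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Construct a per-subject ROI sample set
#'
#' Holds one subject's per-region gray-matter intensity samples. Regions are
#' stored in the order given; use [canonicalize_regions()] to put them into
#' the canonical AAL-90 order.
#'
#' @param subject_id single string.
#' @param samples named list of numeric vectors (one per region).
#' @param min_samples minimum samples required per region (default 30).
#' @return An object of class `roi_sample_set`.
#' @export
roi_sample_set <- function(subject_id, samples, min_samples = 30L) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  if (is.null(names(samples)) || anyDuplicated(names(samples)))
    stop("samples must be a uniquely named list of regions")
  for (rg in names(samples)) {
    v <- samples[[rg]]
    if (!is.numeric(v)) stop("non-numeric samples for region ", rg,
                             " of subject ", subject_id)
    if (!all(is.finite(v))) stop("non-finite samples in region ", rg,
                                 " of subject ", subject_id)
    if (length(v) < min_samples)
      stop("region ", rg, " of subject ", subject_id, " has ", length(v),
           " samples; need >= ", min_samples)
  }
  structure(list(subject_id = subject_id, samples = samples),
            class = "roi_sample_set")
}

#' @export
print.roi_sample_set <- function(x, ...) {
  ns <- lengths(x$samples)
  cat("<roi_sample_set> subject", x$subject_id, "-", length(ns), "regions,",
      min(ns), "-", max(ns), "samples/region\n")
  invisible(x)
}

#' Region names of a sample set
#' @param x an `roi_sample_set`.
#' @export
region_names <- function(x) names(x$samples)

#' Reorder a sample set into canonical AAL-90 order
#'
#' Idempotent; the result is independent of the input region order.
#'
#' @param x an `roi_sample_set` whose regions are AAL-90 names.
#' @return The same object with regions sorted by canonical AAL position.
#' @export
canonicalize_regions <- function(x) {
  pos <- aal90_match(region_names(x))
  x$samples <- x$samples[order(pos)]
  x
}

validate_subject_table <- function(df) {
  required <- c("subject_id", "group", "age", "sex", "medication_code")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("subject table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in subject table")
  bad_grp <- setdiff(unique(df$group), .GROUPS)
  if (length(bad_grp))
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         " (expected HC, MDD, BD)")
  if (!all(df$sex %in% c("M", "F")))
    stop("sex must be coded M/F")
  df$medication_code[is.na(df$medication_code) & df$group == "HC"] <- 1L
  if (!all(df$medication_code %in% 1:3))
    stop("medication_code must be in {1,2,3}")
  for (sc in intersect(c("hamd", "hama", "ymrs"), names(df))) {
    v <- df[[sc]]
    if (any(!is.na(v) & v < 0)) stop(sc, " scores must be non-negative")
  }
  df$group <- factor(df$group, levels = .GROUPS)
  df
}

#' Read a subject table
#'
#' Delimited text (CSV/TSV by extension) with header columns `subject_id`,
#' `group` (HC/MDD/BD), `age`, `sex` (M/F), `medication_code` (1 = none,
#' 2 = antidepressant only, 3 = antidepressant + antipsychotic) and optional
#' clinical scores `hamd`, `hama`, `ymrs`.
#'
#' @param path file path.
#' @return Validated data.frame, `group` as a factor with levels HC, MDD, BD.
#' @export
read_subject_table <- function(path) {
  header <- strsplit(readLines(path, n = 1L), delim_for(path))[[1L]]
  classes <- ifelse(header %in% c("subject_id", "group", "sex"),
                    "character", NA)   # keep sex "F" from becoming logical
  df <- utils::read.csv(path, sep = delim_for(path), stringsAsFactors = FALSE,
                        colClasses = classes)
  validate_subject_table(df)
}

#' Write a subject table
#' @param subjects data.frame as returned by [read_subject_table()].
#' @param path output file path (.csv or .tsv).
#' @export
write_subject_table <- function(subjects, path) {
  utils::write.table(subjects, path, sep = delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read long-format ROI samples
#'
#' Expects delimited text with header `subject_id, region_label, value`, one
#' row per voxel sample. The long format is used because per-region voxel
#' counts differ.
#'
#' @param path file path.
#' @param min_samples minimum samples per region.
#' @return Named list of `roi_sample_set`, one per subject, regions in
#'   canonical AAL order when the labels are AAL names.
#' @export
read_roi_samples <- function(path, min_samples = 30L) {
  df <- utils::read.csv(path, sep = delim_for(path), stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character"))
  need <- c("subject_id", "region_label", "value")
  if (!all(need %in% names(df)))
    stop("samples file must have columns subject_id, region_label, value")
  val <- suppressWarnings(as.numeric(df$value))
  if (anyNA(val)) {
    line <- which(is.na(val))[1L] + 1L  # +1 for the header line
    stop("non-numeric sample value at line ", line, " of ", path)
  }
  out <- list()
  for (sid in unique(df$subject_id)) {
    sub <- df$subject_id == sid
    samples <- split(val[sub], df$region_label[sub])
    ss <- roi_sample_set(sid, samples, min_samples = min_samples)
    if (all(region_names(ss) %in% aal90_names()))
      ss <- canonicalize_regions(ss)
    out[[sid]] <- ss
  }
  out
}

#' Write ROI sample sets in long format
#' @param sample_sets list of `roi_sample_set`.
#' @param path output path (.csv or .tsv).
#' @export
write_roi_samples <- function(sample_sets, path) {
  if (inherits(sample_sets, "roi_sample_set")) sample_sets <- list(sample_sets)
  dfs <- lapply(sample_sets, function(ss) {
    data.frame(subject_id = ss$subject_id,
               region_label = rep(region_names(ss), lengths(ss$samples)),
               value = unlist(ss$samples, use.names = FALSE))
  })
  utils::write.table(do.call(rbind, dfs), path, sep = delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort (subject table + samples), aligned by subject id
#'
#' @param subject_table_path path to the subject table.
#' @param samples_path path to the long-format samples file.
#' @param min_samples minimum samples per region.
#' @return List with `subjects` (data.frame) and `samples` (named list of
#'   `roi_sample_set` in subject-table order).
#' @export
read_cohort <- function(subject_table_path, samples_path, min_samples = 30L) {
  subjects <- read_subject_table(subject_table_path)
  samples <- read_roi_samples(samples_path, min_samples = min_samples)
  orphan <- setdiff(names(samples), subjects$subject_id)
  if (length(orphan))
    stop("subject(s) present in samples but absent from subject table: ",
         paste(orphan, collapse = ", "))
  missing <- setdiff(subjects$subject_id, names(samples))
  if (length(missing))
    stop("subject(s) in table without samples: ",
         paste(missing, collapse = ", "))
  regions <- region_names(samples[[1L]])
  for (ss in samples) {
    gap <- setdiff(regions, region_names(ss))
    if (length(gap))
      stop("subject ", ss$subject_id, " is missing region(s): ",
           paste(gap, collapse = ", "))
  }
  cohort(subjects, samples[subjects$subject_id])
}

#' Assemble a cohort object
#' @param subjects validated subject data.frame.
#' @param samples named list of `roi_sample_set` aligned with `subjects`.
#' @export
cohort <- function(subjects, samples) {
  subjects <- validate_subject_table(subjects)
  stopifnot(identical(subjects$subject_id, names(samples)))
  structure(list(subjects = subjects, samples = samples),
            class = "morphnet_cohort")
}

#' @export
print.morphnet_cohort <- function(x, ...) {
  cat("<morphnet_cohort>", nrow(x$subjects), "subjects (",
      paste(sprintf("%s=%d", levels(x$subjects$group),
                    tabulate(x$subjects$group, 3L)), collapse = ", "),
      "),", length(region_names(x$samples[[1L]])), "regions\n")
  invisible(x)
}

#' Write a cohort to a pair of files
#' @param ch a `morphnet_cohort`.
#' @param subject_table_path,samples_path output paths.
#' @export
write_cohort <- function(ch, subject_table_path, samples_path) {
  write_subject_table(ch$subjects, subject_table_path)
  write_roi_samples(ch$samples, samples_path)
  invisible(ch)
}

#' Write a similarity matrix as labeled CSV
#'
#' @param matrix square symmetric numeric matrix with region dimnames.
#' @param path output path.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix))
  if (is.null(rownames(matrix))) stop("matrix must carry region labels")
  df <- data.frame(region = rownames(matrix),
                   format(matrix, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("region", colnames(matrix))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a similarity matrix written by [write_matrix()]
#'
#' @param path input path.
#' @param tol asymmetry tolerance (default 1e-9).
#' @return Numeric matrix with labels; hard error if non-square or asymmetric
#'   beyond `tol`.
#' @export
read_matrix <- function(path, tol = 1e-9) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!identical(labels, colnames(m)))
    stop("row and column labels disagree in ", path)
  rownames(m) <- labels
  if (max(abs(m - t(m))) > tol)
    stop("matrix in ", path, " is asymmetric beyond tolerance ", tol)
  m
}
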