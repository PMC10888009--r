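# Synthetic cohort generator.
#
# Emulates the statistical structure the pipeline assumes: per-subject,
# per-region gray-matter intensity samples on (0,1) with region-specific
# distribution locations, subject-level morphological variability, optional
# planted between-group distribution shifts, demographic covariates, a
# 3-level medication code and clinical scores. Region base means follow a
# smooth periodic profile over the canonical region index, so that regions
# close in the profile have similar intensity distributions: after KLS
# network construction this yields a ring-lattice-like similarity structure
# whose subject-level jitter adds shortcuts -- i.e. graphs in the small-world
# regime, which is what the estimability validation expects of real
# gray-matter networks.

#' Describe a synthetic cohort
#'
#' @param n_per_group named integer vector of group sizes; names from
#'   HC/MDD/BD. Default mirrors a typical mood-disorder case-control study
#'   (HC = 44, MDD = 43, BD = 32).
#' @param n_regions number of regions (default 90; smaller values use the
#'   first `n_regions` canonical AAL names for reduced test worlds).
#' @param samples_per_region voxel samples per region (default 200).
#' @param base_mean per-region base intensity means in (0,1); default a
#'   smooth periodic profile spanning \[0.3, 0.8\].
#' @param base_sd per-region intensity standard deviations (default 0.08).
#' @param subject_sd standard deviation of the per-subject, per-region mean
#'   jitter (morphological variability between individuals; default 0.02).
#' @param effects data.frame with columns `group`, `region` (canonical
#'   index), `mean_shift`, `sd_scale`: planted group-level distribution
#'   shifts.
#' @param age_mean,age_sd age model (years), truncated at 16.
#' @param p_female probability of sex F.
#' @param medication_probs named list of per-group probability vectors over
#'   medication codes 1 (none), 2 (antidepressant only), 3 (antidepressant +
#'   antipsychotic).
#' @param confound_strength additive effect of `medication_code - 1` on the
#'   region means (weighted by a fixed smooth profile); 0 disables it.
#' @param score_coupling optional list(`region`, `slope`): couples the HAMD
#'   score to the subject's realized mean deviation in one region.
#' @param seed global integer seed; fans out to per-subject substreams so
#'   adding subjects never perturbs earlier subjects' draws.
#' @return Object of class `cohort_design`.
#' @export
cohort_design <- function(n_per_group = c(HC = 44L, MDD = 43L, BD = 32L),
                          n_regions = 90L,
                          samples_per_region = 200L,
                          base_mean = NULL,
                          base_sd = NULL,
                          subject_sd = 0.02,
                          effects = NULL,
                          age_mean = 21.5, age_sd = 10,
                          p_female = 0.75,
                          medication_probs = list(
                            HC = c(1, 0, 0),
                            MDD = c(0.09, 0.61, 0.30),
                            BD = c(0.13, 0.47, 0.40)),
                          confound_strength = 0,
                          score_coupling = NULL,
                          seed = 1L) {
  stopifnot(length(n_per_group) >= 1L, all(n_per_group > 0))
  groups <- names(n_per_group)
  if (is.null(groups) || !all(groups %in% .GROUPS))
    stop("n_per_group must be named with groups among HC, MDD, BD")
  n_regions <- as.integer(n_regions)
  stopifnot(n_regions >= 2L, n_regions <= 90L, samples_per_region >= 30L)
  if (is.null(base_mean))
    base_mean <- 0.55 + 0.25 * sin(2 * pi * (seq_len(n_regions) - 1) /
                                     n_regions)
  if (is.null(base_sd)) base_sd <- rep(0.08, n_regions)
  base_sd <- rep_len(base_sd, n_regions)
  stopifnot(length(base_mean) == n_regions, all(base_mean > 0 & base_mean < 1),
            all(base_sd > 0))
  if (is.null(effects))
    effects <- data.frame(group = character(), region = integer(),
                          mean_shift = numeric(), sd_scale = numeric())
  stopifnot(all(c("group", "region", "mean_shift") %in% names(effects)))
  if (!"sd_scale" %in% names(effects)) effects$sd_scale <- 1
  if (nrow(effects)) {
    stopifnot(all(effects$group %in% groups),
              all(effects$region >= 1L & effects$region <= n_regions),
              all(effects$sd_scale > 0))
  }
  for (g in groups) {
    p <- medication_probs[[g]]
    if (is.null(p) || length(p) != 3L || abs(sum(p) - 1) > 1e-9)
      stop("medication_probs for group ", g,
           " must be 3 probabilities summing to 1")
  }
  structure(list(n_per_group = n_per_group, n_regions = n_regions,
                 samples_per_region = as.integer(samples_per_region),
                 base_mean = base_mean, base_sd = base_sd,
                 subject_sd = subject_sd, effects = effects,
                 age_mean = age_mean, age_sd = age_sd, p_female = p_female,
                 medication_probs = medication_probs,
                 confound_strength = confound_strength,
                 score_coupling = score_coupling,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("<cohort_design>", sum(x$n_per_group), "subjects (",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
            collapse = ", "), "),", x$n_regions, "regions x",
      x$samples_per_region, "samples,", nrow(x$effects),
      "planted effect(s), seed", x$seed, "\n")
  invisible(x)
}

# deterministic per-subject substream seed (stays below 2^31 - 1)
subject_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 65011) * 33029 + i * 7919) %% 2147483562L + 1L
}

rtruncnorm01 <- function(n, mean, sd) {
  pmin(pmax(stats::rnorm(n, mean, sd), 1e-4), 1 - 1e-4)
}

# fixed smooth profile weighting the medication confound across regions
confound_weights <- function(n_regions) {
  0.5 * (1 + cos(2 * pi * (seq_len(n_regions) - 1) / n_regions))
}

#' Generate a synthetic cohort
#'
#' Deterministic given the design's seed. Each subject's per-region samples
#' are truncated-normal draws on (0,1) around `base_mean` plus a per-subject
#' jitter, the subject's group effects, and (when `confound_strength > 0`)
#' an additive medication effect. Ages, sexes, medication codes and clinical
#' scores are drawn per the design's models (HAMD/HAMA for patient groups,
#' YMRS for BD only).
#'
#' @param design a [cohort_design()].
#' @return A `morphnet_cohort` (see [cohort()]).
#' @export
generate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  groups <- names(design$n_per_group)
  ids <- character(0)
  grp <- character(0)
  for (g in groups) {
    k <- design$n_per_group[[g]]
    ids <- c(ids, sprintf("%s%03d", g, seq_len(k)))
    grp <- c(grp, rep(g, k))
  }
  n <- length(ids)
  R <- design$n_regions
  regions <- aal90_names()[seq_len(R)]
  cw <- confound_weights(R)
  subjects <- data.frame(subject_id = ids, group = grp,
                         age = NA_real_, sex = NA_character_,
                         medication_code = NA_integer_,
                         hamd = NA_real_, hama = NA_real_, ymrs = NA_real_,
                         stringsAsFactors = FALSE)
  samples <- vector("list", n)
  names(samples) <- ids
  for (i in seq_len(n)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(subject_seed(design$seed, i))
    g <- grp[i]
    age <- max(stats::rnorm(1L, design$age_mean, design$age_sd), 16)
    sex <- if (stats::runif(1L) < design$p_female) "F" else "M"
    med <- sample.int(3L, 1L, prob = design$medication_probs[[g]])
    mu <- design$base_mean +
      stats::rnorm(R, 0, design$subject_sd) +
      design$confound_strength * (med - 1L) * cw
    sdv <- design$base_sd
    eff <- design$effects[design$effects$group == g, , drop = FALSE]
    if (nrow(eff)) {
      mu[eff$region] <- mu[eff$region] + eff$mean_shift
      sdv <- replace(sdv, eff$region, sdv[eff$region] * eff$sd_scale)
    }
    subj_samples <- lapply(seq_len(R), function(r)
      rtruncnorm01(design$samples_per_region, mu[r], sdv[r]))
    names(subj_samples) <- regions
    # clinical scores: patients only; YMRS for BD only
    hamd <- hama <- ymrs <- NA_real_
    if (g %in% c("MDD", "BD")) {
      hamd <- 27 + stats::rnorm(1L, 0, 9)
      if (!is.null(design$score_coupling)) {
        sc <- design$score_coupling
        dev <- (mu[sc$region] - design$base_mean[sc$region]) /
          design$subject_sd
        hamd <- hamd + sc$slope * dev
      }
      hamd <- max(hamd, 0)
      hama <- max(17 + stats::rnorm(1L, 0, 7), 0)
      if (g == "BD") ymrs <- max(27 + stats::rnorm(1L, 0, 8), 0)
    }
    subjects$age[i] <- age
    subjects$sex[i] <- sex
    subjects$medication_code[i] <- med
    subjects$hamd[i] <- hamd
    subjects$hama[i] <- hama
    subjects$ymrs[i] <- ymrs
    samples[[i]] <- roi_sample_set(ids[i], subj_samples,
                                   min_samples = min(30L, design$samples_per_region))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  }
  cohort(subjects, samples)
}

#' Generate a null cohort (no planted effects)
#'
#' Convenience wrapper used for type-I-error calibration: all groups are
#' exchangeable by construction.
#'
#' @param n_per_group named group sizes (each at least 2).
#' @param seed integer seed.
#' @param ... further arguments to [cohort_design()].
#' @return A `morphnet_cohort`.
#' @export
generate_null_cohort <- function(n_per_group, seed, ...) {
  if (any(n_per_group < 2L)) stop("each group needs at least 2 subjects")
  generate_cohort(cohort_design(n_per_group = n_per_group, effects = NULL,
                                seed = seed, ...))
}
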