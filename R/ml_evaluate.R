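# Cross-validated evaluation of the reducer x classifier cascade.
#
# Everything data-dependent -- confound residualization, standardization,
# dimensionality reduction, classifier fitting -- happens inside the training
# fold only; test folds are used exclusively for prediction. Headline rates
# come from the confusion counts pooled over folds; fold-mean balanced
# accuracy is also reported for comparability with studies that average
# folds.

#' Stratified fold assignment
#'
#' @param y binary 0/1 labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @return Integer fold id (1..k) per observation; every fold contains both
#'   classes provided each class has at least `k` members.
#' @export
stratified_folds <- function(y, k = 5L, seed = 1L) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Build a classification task from cohort matrices
#'
#' @param matrices named list of per-subject similarity matrices.
#' @param subjects subject table aligned by `subject_id`.
#' @param task `"hc-vs-patients"` (positive class = BD or MDD) or
#'   `"bd-vs-mdd"` (positive class = BD).
#' @param features `"full"` (all regions) or `"submatrix"` (the 15-region
#'   BD-vs-MDD subset, see [bd_mdd_subregions()]).
#' @return List with `features` matrix, `y` (0/1), `confound` (medication
#'   code), `subject_ids`, `positive` (class mapped to 1).
#' @export
make_task <- function(matrices, subjects,
                      task = c("hc-vs-patients", "bd-vs-mdd"),
                      features = c("full", "submatrix")) {
  task <- match.arg(task)
  features <- match.arg(features)
  stopifnot(all(names(matrices) %in% subjects$subject_id))
  subjects <- subjects[match(names(matrices), subjects$subject_id), ]
  grp <- as.character(subjects$group)
  if (task == "hc-vs-patients") {
    keep <- rep(TRUE, length(grp))
    y <- as.integer(grp %in% c("BD", "MDD"))
    positive <- "BD+MDD"
  } else {
    keep <- grp %in% c("BD", "MDD")
    y <- as.integer(grp[keep] == "BD")
    positive <- "BD"
  }
  subset <- if (features == "submatrix") bd_mdd_subregions() else NULL
  ft <- vectorize(matrices[keep], region_subset = subset)
  list(features = ft$features, y = y,
       confound = subjects$medication_code[keep],
       subject_ids = ft$subject_ids, positive = positive, task = task,
       provenance = ft$provenance)
}

standardizer <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sdv = sdv)
}

apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2L, std$mu), 2L, std$sdv, "/")
}

#' Cross-validated evaluation of one reducer x classifier cell
#'
#' 5-fold stratified cross-validation: per fold, the medication confound is
#' residualized with training-fold GPs, features are standardized with
#' training statistics, the optional reducer is fitted on the training fold,
#' and the classifier is trained and applied to the held-out fold. Confusion
#' counts are pooled across folds.
#'
#' @param X feature matrix (subjects x features).
#' @param y binary 0/1 labels (1 = positive class; sensitivity = detection
#'   rate of class 1).
#' @param confound optional medication codes for GP residualization.
#' @param reducer `"none"`, `"AE"` or `"DNN"`.
#' @param classifier `"SVM"`, `"RF"` or `"XGB"`.
#' @param k_folds folds (default 5).
#' @param seed integer seed (fold assignment, reducer init, tree draws).
#' @param dim reducer bottleneck width (default: 64 for wide inputs, 16
#'   otherwise).
#' @param epochs reducer training budget.
#' @param classifier_args list of overrides passed to [fit_classifier()].
#' @return Object of class `classification_report`: balanced accuracy,
#'   sensitivity, specificity from pooled counts, per-fold balanced
#'   accuracies and their mean, and the pooled confusion counts.
#' @export
evaluate <- function(X, y, confound = NULL, reducer = "none",
                     classifier = "SVM", k_folds = 5L, seed = 1L,
                     dim = NULL, epochs = 200L, classifier_args = list()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0L, 1L)))
  if (min(tabulate(y + 1L, 2L)) < k_folds)
    stop("need at least k_folds subjects per class")
  folds <- stratified_folds(y, k_folds, seed)
  tp <- fn <- tn <- fp <- 0L
  fold_bac <- numeric(k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2L || !any(te))
      stop("a class is absent from a training fold")
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
    if (!is.null(confound)) {
      gp <- fit_confound_gp(Xtr, confound[tr])
      Xtr <- residualize_confound(gp, Xtr, confound[tr])
      Xte <- residualize_confound(gp, Xte, confound[te])
    }
    std <- standardizer(Xtr)
    Xtr <- apply_standardizer(std, Xtr)
    Xte <- apply_standardizer(std, Xte)
    if (reducer != "none") {
      red <- fit_reducer(reducer, Xtr, y = y[tr], dim = dim,
                         seed = seed + 1000L * f, epochs = epochs)
      Xtr <- apply_reducer(red, Xtr)
      Xte <- apply_reducer(red, Xte)
    }
    model <- do.call(fit_classifier,
                     c(list(kind = classifier, X = Xtr, y01 = y[tr],
                            seed = seed + f), classifier_args))
    pred <- predict_classifier(model, Xte)
    yt <- y[te]
    ftp <- sum(pred == 1L & yt == 1L); ffn <- sum(pred == 0L & yt == 1L)
    ftn <- sum(pred == 0L & yt == 0L); ffp <- sum(pred == 1L & yt == 0L)
    tp <- tp + ftp; fn <- fn + ffn; tn <- tn + ftn; fp <- fp + ffp
    fsens <- if (ftp + ffn > 0) ftp / (ftp + ffn) else NA_real_
    fspec <- if (ftn + ffp > 0) ftn / (ftn + ffp) else NA_real_
    fold_bac[f] <- mean(c(fsens, fspec), na.rm = TRUE)
  }
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  structure(list(reducer = reducer, classifier = classifier,
                 balanced_accuracy = (sens + spec) / 2,
                 sensitivity = sens, specificity = spec,
                 fold_balanced_accuracy = fold_bac,
                 fold_mean_balanced_accuracy = mean(fold_bac),
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 k_folds = k_folds, seed = seed),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s + %s: BAC %.3f (sens %.3f, spec %.3f)\n",
              x$reducer, x$classifier, x$balanced_accuracy, x$sensitivity,
              x$specificity))
  if (!is.null(x$p_perm)) cat("  label-permutation p =", format(x$p_perm), "\n")
  invisible(x)
}

#' Label-permutation validation of a classification pipeline
#'
#' Shuffles the labels `n_perm` times, reruns the full cross-validated
#' cascade, and reports `p = (1 + #{permuted BAC >= observed BAC}) /
#' (n_perm + 1)`.
#'
#' @param X,y,confound,reducer,classifier,k_folds,seed,dim,epochs,classifier_args
#'   as in [evaluate()].
#' @param n_perm number of label permutations (>= 99; default 1000).
#' @return The observed `classification_report` with `p_perm` and
#'   `perm_bac` (the permuted balanced accuracies) added.
#' @export
label_permutation_test <- function(X, y, confound = NULL, reducer = "none",
                                   classifier = "SVM", n_perm = 1000L,
                                   k_folds = 5L, seed = 1L, dim = NULL,
                                   epochs = 200L, classifier_args = list()) {
  stopifnot(n_perm >= 99L)
  obs <- evaluate(X, y, confound = confound, reducer = reducer,
                  classifier = classifier, k_folds = k_folds, seed = seed,
                  dim = dim, epochs = epochs,
                  classifier_args = classifier_args)
  perm_bac <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    set.seed(seed + 7919L * b)
    yp <- sample(y)
    rep_b <- evaluate(X, yp, confound = confound, reducer = reducer,
                      classifier = classifier, k_folds = k_folds,
                      seed = seed, dim = dim, epochs = epochs,
                      classifier_args = classifier_args)
    perm_bac[b] <- rep_b$balanced_accuracy
  }
  obs$p_perm <- (1 + sum(perm_bac >= obs$balanced_accuracy)) / (n_perm + 1)
  obs$perm_bac <- perm_bac
  obs
}

#' Run the full reducer x classifier grid on one task
#'
#' @param task a task list from [make_task()] (or any list with `features`,
#'   `y`, `confound`).
#' @param reducers,classifiers grid axes (defaults: the full 3 x 3 grid).
#' @param n_perm label permutations per cell (0 = skip the permutation test).
#' @param ... passed to [evaluate()].
#' @return data.frame with one row per cell: reducer, classifier, balanced
#'   accuracy, sensitivity, specificity, fold-mean balanced accuracy, and
#'   `p_perm` when requested.
#' @export
classification_grid <- function(task, reducers = c("none", "AE", "DNN"),
                                classifiers = c("SVM", "RF", "XGB"),
                                n_perm = 0L, ...) {
  rows <- list()
  for (rd in reducers) for (cl in classifiers) {
    rep_ <- if (n_perm > 0L)
      label_permutation_test(task$features, task$y, confound = task$confound,
                             reducer = rd, classifier = cl, n_perm = n_perm,
                             ...)
    else
      evaluate(task$features, task$y, confound = task$confound, reducer = rd,
               classifier = cl, ...)
    rows[[length(rows) + 1L]] <- data.frame(
      reducer = rd, classifier = cl,
      balanced_accuracy = rep_$balanced_accuracy,
      sensitivity = rep_$sensitivity, specificity = rep_$specificity,
      fold_mean_balanced_accuracy = rep_$fold_mean_balanced_accuracy,
      p_perm = if (is.null(rep_$p_perm)) NA_real_ else rep_$p_perm,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
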