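# Apparent (resubstitution) evaluation and the three resampling schemes.
#
# Every scheme fits references/thresholds on a training subset (or
# multiset) and pools all held-out predictions into one confusion matrix
# (micro-averaging), which is stable with classes as small as 21 patients.
# Cross-validated metrics always use the three-way decision rule; the
# apparent evaluation additionally reports the two pairwise comparisons
# with dedicated two-candidate decisions.

# Fit the selected method on the weighted training multiset and predict
# the eval_idx patients. forbid_ids, when given, asserts reference hygiene:
# no held-out patient may contribute to a fitted reference.
fit_and_predict <- function(ch, method, alpha, weights, eval_idx,
                            candidate_classes = CLASS_LEVELS,
                            forbid_ids = NULL) {
  if (method == "histogram") {
    refs <- fit_all_references(ch, alpha, weights = weights)
    if (!is.null(forbid_ids)) {
      for (r in refs)
        if (any(forbid_ids %in% r$source_patient_ids))
          stop("internal error: held-out patient leaked into a reference")
    }
    predict_chi2(ch, refs, eval_idx, candidate_classes)
  } else if (method == "mean") {
    model <- fit_mean_classifier(ch$mean_adc, ch$true_class, ch$patient_id,
                                 weights = weights)
    if (!is.null(forbid_ids) && any(forbid_ids %in% model$source_patient_ids))
      stop("internal error: held-out patient leaked into the threshold fit")
    classify_mean(ch$mean_adc[eval_idx], model, candidate_classes)
  } else stop("`method` must be \"histogram\" or \"mean\"", call. = FALSE)
}

#' Apparent (resubstitution) performance
#'
#' References and thresholds are fitted on the full cohort and every
#' patient is then classified with them, so the evaluated cases also
#' calibrated the classifier — this is the optimistic companion to the
#' cross-validated estimates. Three-way predictions drive the confusion
#' matrix and the MT-versus-benign comparison; the MT-versus-PA and
#' MT-versus-WT rows come from dedicated two-candidate decisions on the
#' patients of those two true classes.
#'
#' @param ch A [cohort_histograms()] object.
#' @param method `"histogram"` (chi-squared discrepancy) or `"mean"`
#'   (Youden thresholds on mean ADC).
#' @param alpha Reference smoothing pseudo-count (histogram method).
#' @return A `metrics_report` with `scheme = "apparent"`.
#' @export
apparent_metrics <- function(ch, method = c("histogram", "mean"), alpha = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(ch, "cohort_histograms"))
  n <- length(ch$patient_id)
  w <- rep(1L, n)
  pred3 <- fit_and_predict(ch, method, alpha, w, seq_len(n))
  pairwise <- list(
    MT_vs_benign = pairwise_sens_spec(ch$true_class, pred3, "MT_vs_benign"))
  for (cmp in c("MT_vs_PA", "MT_vs_WT")) {
    benign <- sub("MT_vs_", "", cmp)
    idx <- which(ch$true_class %in% c("MT", benign))
    pred2 <- fit_and_predict(ch, method, alpha, w, idx,
                             candidate_classes = c(benign, "MT"))
    pairwise[[cmp]] <- pairwise_sens_spec(ch$true_class[idx], pred2, cmp)
  }
  new_metrics_report(ch$true_class, pred3, "apparent", pairwise = pairwise,
                     config = list(method = method, alpha = alpha))
}

#' Leave-one-out cross-validation
#'
#' Each patient is held out once; references/thresholds are refitted on the
#' remaining patients and the held-out patient is classified three-way.
#' Deterministic: no randomness is involved. Every class must retain at
#' least one patient after each exclusion (so at least 2 per class).
#'
#' @inheritParams apparent_metrics
#' @return A `metrics_report` with `scheme = "loocv"` pooling all `n`
#'   held-out predictions.
#' @export
loocv <- function(ch, method = c("histogram", "mean"), alpha = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(ch, "cohort_histograms"))
  counts <- table(factor(ch$true_class, levels = CLASS_LEVELS))
  if (any(counts < 2L))
    stop("leave-one-out needs at least 2 patients per class", call. = FALSE)
  n <- length(ch$patient_id)
  pred <- character(n)
  for (i in seq_len(n)) {
    w <- rep(1L, n); w[i] <- 0L
    pred[i] <- fit_and_predict(ch, method, alpha, w, i,
                               forbid_ids = ch$patient_id[i])
  }
  new_metrics_report(ch$true_class, pred, "loocv",
                     config = list(method = method, alpha = alpha))
}

# Stratified fold assignment: within each class, patients are dealt (in
# random order) into the currently lightest-loaded folds, so folds are
# balanced both per class and overall. With k = n this reduces to one
# patient per fold, i.e. leave-one-out.
assign_folds <- function(classes, k) {
  n <- length(classes)
  fold <- integer(n)
  load <- integer(k)
  for (cl in CLASS_LEVELS) {
    idx <- which(classes == cl)
    if (!length(idx)) next
    idx <- idx[sample.int(length(idx))]
    ord <- sample.int(k)            # random tie-break among equal loads
    ord <- ord[order(load[ord])]    # lightest folds first (stable)
    quota <- integer(k)
    base <- length(idx) %/% k
    extra <- length(idx) %% k
    quota[ord] <- base + rep(c(1L, 0L), c(extra, k - extra))
    fold[idx] <- rep.int(seq_len(k), quota)
    load <- load + quota
  }
  fold
}

#' Repeated stratified k-fold cross-validation
#'
#' Per repeat, patients are partitioned into `k` class-stratified folds;
#' each fold is classified three-way by a model fitted on its complement.
#' All held-out predictions across folds and repeats are pooled into one
#' confusion matrix. Fully reproducible from `seed`. With `k = n` and
#' `repeats = 1` the result coincides with [loocv()].
#'
#' @inheritParams apparent_metrics
#' @param k Number of folds, `>= 2`. Default 10.
#' @param repeats Number of repeats. Default 1000 (the conventional choice
#'   for stabilizing small-cohort estimates); tests and examples use far
#'   fewer.
#' @param seed Integer RNG seed.
#' @return A `metrics_report` with `scheme = "repeated_cv"`.
#' @export
repeated_kfold <- function(ch, method = c("histogram", "mean"), alpha = 0.5,
                           k = 10, repeats = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(ch, "cohort_histograms"))
  if (!is.numeric(k) || length(k) != 1L || k < 2 || k != round(k))
    stop("`k` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(repeats) || repeats < 1 || repeats != round(repeats))
    stop("`repeats` must be a positive integer", call. = FALSE)
  n <- length(ch$patient_id)
  if (k > n) stop("`k` cannot exceed the number of patients", call. = FALSE)
  set.seed(seed)
  true_all <- vector("list", repeats * k)
  pred_all <- vector("list", repeats * k)
  slot <- 0L
  for (r in seq_len(repeats)) {
    fold <- assign_folds(ch$true_class, k)
    for (j in seq_len(k)) {
      test <- which(fold == j)
      if (!length(test)) next
      w <- as.integer(fold != j)
      slot <- slot + 1L
      true_all[[slot]] <- ch$true_class[test]
      pred_all[[slot]] <- fit_and_predict(ch, method, alpha, w, test,
                                          forbid_ids = ch$patient_id[test])
    }
  }
  new_metrics_report(unlist(true_all), unlist(pred_all), "repeated_cv",
                     config = list(method = method, alpha = alpha, k = k,
                                   repeats = repeats, seed = seed))
}

#' Out-of-bag bootstrap cross-validation
#'
#' Per iteration, a training multiset of `n` patients is drawn with
#' replacement, stratified by class (each class is resampled to its own
#' size, so no class can disappear). Patients never drawn — the out-of-bag
#' set — are classified three-way by the model fitted on the multiset, in
#' which a patient drawn twice carries double weight. All out-of-bag
#' predictions are pooled across iterations; iterations whose out-of-bag
#' set is empty are skipped and counted in the report diagnostics.
#'
#' @inheritParams apparent_metrics
#' @param iterations Number of bootstrap iterations. Default 1000.
#' @param seed Integer RNG seed.
#' @return A `metrics_report` with `scheme = "bootstrap"`;
#'   `diagnostics$skipped_iterations` counts empty out-of-bag draws.
#' @export
bootstrap_cv <- function(ch, method = c("histogram", "mean"), alpha = 0.5,
                         iterations = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(ch, "cohort_histograms"))
  if (!is.numeric(iterations) || iterations < 1 || iterations != round(iterations))
    stop("`iterations` must be a positive integer", call. = FALSE)
  set.seed(seed)
  n <- length(ch$patient_id)
  class_idx <- lapply(CLASS_LEVELS, function(cl) which(ch$true_class == cl))
  true_all <- vector("list", iterations)
  pred_all <- vector("list", iterations)
  skipped <- 0L
  for (b in seq_len(iterations)) {
    w <- integer(n)
    for (ci in class_idx) {
      draw <- ci[sample.int(length(ci), length(ci), replace = TRUE)]
      w <- w + tabulate(draw, nbins = n)
    }
    oob <- which(w == 0L)
    if (!length(oob)) { skipped <- skipped + 1L; next }
    true_all[[b]] <- ch$true_class[oob]
    pred_all[[b]] <- fit_and_predict(ch, method, alpha, w, oob,
                                     forbid_ids = ch$patient_id[oob])
  }
  new_metrics_report(unlist(true_all), unlist(pred_all), "bootstrap",
                     diagnostics = list(skipped_iterations = skipped),
                     config = list(method = method, alpha = alpha,
                                   iterations = iterations, seed = seed))
}
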