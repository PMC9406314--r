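# Mean-ADC comparator: Youden-index-optimal thresholds.
#
# The clinical-routine baseline classifies on the whole-lesion mean ADC.
# Two separate thresholds are calibrated, MT versus PA and MT versus WT,
# because the two benign entities sit on opposite sides of the malignant
# band (PA high, WT low); a single benign threshold would be forced through
# the middle of one of them.

#' Fit a Youden-index-optimal mean-ADC threshold for one class pair
#'
#' Candidate cuts are the midpoints between consecutive distinct values of
#' the pooled sorted means, plus one sentinel cut below the minimum and one
#' above the maximum (so "predict nobody MT" and "predict everybody MT" are
#' reachable). Both orientations are evaluated at every cut; the pair
#' maximizing `J = sensitivity + specificity - 1` wins. Ties are broken
#' toward the smaller cut, then toward `MT_if_leq`.
#'
#' @param means_positive Mean ADC values of the positive class (MT).
#' @param means_negative Mean ADC values of the negative class (PA or WT).
#' @param pair Label recorded on the result: `"MT_vs_PA"` or `"MT_vs_WT"`.
#' @return A `threshold_spec`: `pair`, `cut`, `orientation` (`"MT_if_leq"`
#'   or `"MT_if_geq"`), `youden` (the maximal J on the fitting data).
#' @export
fit_youden_threshold <- function(means_positive, means_negative,
                                 pair = c("MT_vs_PA", "MT_vs_WT")) {
  pair <- match.arg(pair)
  if (length(means_positive) == 0L || length(means_negative) == 0L)
    stop("both classes must be non-empty", call. = FALSE)
  pooled <- sort(unique(c(means_positive, means_negative)))
  cuts <- c(pooled[1L] - 1,
            if (length(pooled) > 1L)
              (pooled[-length(pooled)] + pooled[-1L]) / 2,
            pooled[length(pooled)] + 1)
  best <- NULL
  for (cut in cuts) {
    for (orientation in c("MT_if_leq", "MT_if_geq")) {
      if (orientation == "MT_if_leq") {
        sens <- mean(means_positive <= cut)
        spec <- mean(means_negative > cut)
      } else {
        sens <- mean(means_positive >= cut)
        spec <- mean(means_negative < cut)
      }
      J <- sens + spec - 1
      if (is.null(best) || J > best$youden + 1e-12)
        best <- list(pair = pair, cut = cut, orientation = orientation,
                     youden = J)
      # ties: cuts are visited in increasing order and MT_if_leq first,
      # so the first maximum encountered is the tie-broken winner
    }
  }
  structure(best, class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("%s threshold: %s %g (J = %.3f)\n", x$pair,
              if (x$orientation == "MT_if_leq") "MT if mean <=" else "MT if mean >=",
              x$cut, x$youden))
  invisible(x)
}

# Apply one threshold_spec to a vector of means; returns "MT" or the
# benign class named in the pair.
apply_threshold <- function(means, spec) {
  benign <- sub("MT_vs_", "", spec$pair)
  is_mt <- if (spec$orientation == "MT_if_leq") means <= spec$cut else means >= spec$cut
  ifelse(is_mt, "MT", benign)
}

#' Fit the two-threshold mean-ADC classifier
#'
#' @param means Numeric vector of per-patient mean ADC values.
#' @param classes Character vector of true classes, parallel to `means`.
#' @param patient_ids Optional ids parallel to `means` (needed for
#'   exclusion and provenance).
#' @param exclude_patient_ids Patients left out of both threshold fits.
#' @param weights Optional non-negative integer multiplicities (bootstrap
#'   resamples); overrides `exclude_patient_ids`.
#' @return A `mean_classifier_model` with `threshold_MT_PA`,
#'   `threshold_MT_WT` and `source_patient_ids`.
#' @export
fit_mean_classifier <- function(means, classes, patient_ids = NULL,
                                exclude_patient_ids = character(),
                                weights = NULL) {
  n <- length(means)
  stopifnot(length(classes) == n)
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(n))
  if (is.null(weights)) {
    weights <- as.integer(!(patient_ids %in% exclude_patient_ids))
  } else {
    if (length(weights) != n || any(weights < 0) || any(weights != round(weights)))
      stop("`weights` must be non-negative integers, one per patient", call. = FALSE)
    weights <- as.integer(weights)
  }
  for (cl in CLASS_LEVELS)
    if (!any(classes == cl & weights > 0L))
      stop(sprintf("class %s has no patients left after exclusion", cl),
           call. = FALSE)
  expand <- function(cl) rep(means[classes == cl], weights[classes == cl])
  mt <- expand("MT")
  structure(
    list(threshold_MT_PA = fit_youden_threshold(mt, expand("PA"), "MT_vs_PA"),
         threshold_MT_WT = fit_youden_threshold(mt, expand("WT"), "MT_vs_WT"),
         source_patient_ids = sort(patient_ids[weights > 0L])),
    class = "mean_classifier_model"
  )
}

#' @export
print.mean_classifier_model <- function(x, ...) {
  print(x$threshold_MT_PA); print(x$threshold_MT_WT)
  invisible(x)
}

#' Classify patients from their mean ADC
#'
#' In pairwise mode (`candidate_classes` is `c("PA","MT")` or
#' `c("WT","MT")`) the single relevant threshold decides. In three-way mode
#' a patient is MT only if both thresholds vote MT; if exactly one benign
#' vote fires, that benign class is assigned; if both benign votes fire,
#' the class whose threshold the mean clears by the larger margin wins,
#' ties going to PA. This combination rule is this package's own
#' construction: only the two pairwise thresholds are standard, and the
#' rule is the minimal one consistent with the WT-low / MT-middle / PA-high
#' band structure.
#'
#' @param means Numeric vector of mean ADC values.
#' @param model A fitted `mean_classifier_model`.
#' @param candidate_classes Subset of `c("PA","WT","MT")`, size >= 2.
#' @return Character vector of predicted classes.
#' @export
classify_mean <- function(means, model, candidate_classes = CLASS_LEVELS) {
  if (!inherits(model, "mean_classifier_model"))
    stop("`model` must be a fitted mean_classifier_model", call. = FALSE)
  candidate_classes <- CLASS_LEVELS[CLASS_LEVELS %in% candidate_classes]
  if (length(candidate_classes) < 2L)
    stop("at least two candidate classes are required", call. = FALSE)
  if (length(candidate_classes) == 2L) {
    if (setequal(candidate_classes, c("PA", "MT")))
      return(apply_threshold(means, model$threshold_MT_PA))
    if (setequal(candidate_classes, c("WT", "MT")))
      return(apply_threshold(means, model$threshold_MT_WT))
    stop("pairwise mean classification is defined for MT vs PA and MT vs WT only",
         call. = FALSE)
  }
  vote_pa <- apply_threshold(means, model$threshold_MT_PA)  # "MT" or "PA"
  vote_wt <- apply_threshold(means, model$threshold_MT_WT)  # "MT" or "WT"
  margin_pa <- abs(means - model$threshold_MT_PA$cut)
  margin_wt <- abs(means - model$threshold_MT_WT$cut)
  out <- character(length(means))
  both_mt <- vote_pa == "MT" & vote_wt == "MT"
  only_pa <- vote_pa == "PA" & vote_wt == "MT"
  only_wt <- vote_pa == "MT" & vote_wt == "WT"
  both_benign <- vote_pa == "PA" & vote_wt == "WT"
  out[both_mt] <- "MT"
  out[only_pa] <- "PA"
  out[only_wt] <- "WT"
  out[both_benign] <- ifelse(margin_wt[both_benign] > margin_pa[both_benign],
                             "WT", "PA")
  out
}
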