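# Pooled class-conditional reference distributions.
#
# Pooling treats every voxel as one observation: per-class bin counts are
# summed over patients, so a patient with twice the voxels carries twice the
# weight. Additive (Laplace) smoothing keeps every expected count positive
# so the chi-squared discrepancy stays finite.

#' Fit a pooled reference PMF for one tumor class
#'
#' Sums the bin counts of all supplied histograms and normalizes with an
#' additive pseudo-count `alpha` per bin:
#' `p_m = (sum_i O_m(i) + alpha) / (sum_i N(i) + alpha * n_bins)`.
#'
#' @param histograms Non-empty list of `adc_histogram` objects from one
#'   class, all sharing one binning scheme.
#' @param alpha Non-negative smoothing pseudo-count per bin. Default 0.5.
#'   With `alpha = 0` empty bins keep probability zero (see
#'   [chi2_statistic()] for how zero expected counts are handled).
#' @param tumor_class Optional class label (`"PA"`, `"WT"` or `"MT"`)
#'   recorded on the fitted object.
#' @return An `adc_reference`: `tumor_class`, `scheme`, `probs` (sums to 1),
#'   `alpha`, `source_patient_ids`.
#' @export
fit_reference <- function(histograms, alpha = 0.5, tumor_class = NA_character_) {
  if (length(histograms) == 0L)
    stop("`histograms` must be non-empty", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha < 0)
    stop("`alpha` must be a single non-negative number", call. = FALSE)
  scheme <- histograms[[1L]]$scheme
  for (h in histograms) {
    stopifnot(inherits(h, "adc_histogram"))
    if (!same_scheme(h$scheme, scheme))
      stop("all histograms must share one binning scheme", call. = FALSE)
  }
  sums <- Reduce(`+`, lapply(histograms, `[[`, "counts"))
  total <- sum(vapply(histograms, `[[`, integer(1), "total"))
  new_reference(tumor_class, scheme, sums, total, alpha,
                vapply(histograms, `[[`, character(1), "patient_id"))
}

new_reference <- function(tumor_class, scheme, sums, total, alpha, ids) {
  probs <- (sums + alpha) / (total + alpha * scheme$n_bins)
  structure(
    list(tumor_class = tumor_class, scheme = scheme, probs = probs,
         alpha = alpha, source_patient_ids = sort(unique(ids))),
    class = "adc_reference"
  )
}

#' @export
print.adc_reference <- function(x, ...) {
  cat(sprintf("Reference PMF for %s: %d bins, alpha = %g, pooled from %d patients\n",
              x$tumor_class, x$scheme$n_bins, x$alpha,
              length(x$source_patient_ids)))
  invisible(x)
}

#' Expected bin counts for a patient under a reference distribution
#'
#' @param ref An `adc_reference`.
#' @param patient_total The patient's voxel count `N(i)`, a positive integer.
#' @return Numeric vector `E_m = N(i) * p_m`; sums to `patient_total`.
#' @export
expected_counts <- function(ref, patient_total) {
  stopifnot(inherits(ref, "adc_reference"))
  if (!is.numeric(patient_total) || length(patient_total) != 1L ||
      patient_total < 1 || patient_total != round(patient_total))
    stop("`patient_total` must be a positive integer", call. = FALSE)
  as.numeric(patient_total) * ref$probs
}

#' Fit all three class references from a binned cohort
#'
#' Fits one pooled reference per tumor class, optionally excluding patients
#' (the cross-validation contract: held-out patients must not contribute to
#' any reference they are scored against).
#'
#' @param ch A [cohort_histograms()] object.
#' @param alpha Smoothing pseudo-count per bin (see [fit_reference()]).
#' @param exclude_patient_ids Character vector of patient ids to leave out
#'   of every reference.
#' @param weights Optional non-negative integer multiplicities, one per
#'   patient column of `ch` (bootstrap resamples draw patients with
#'   replacement); overrides `exclude_patient_ids` when given. Weight zero
#'   excludes a patient.
#' @return Named list `list(PA = , WT = , MT = )` of `adc_reference`.
#' @export
fit_all_references <- function(ch, alpha = 0.5,
                               exclude_patient_ids = character(),
                               weights = NULL) {
  stopifnot(inherits(ch, "cohort_histograms"))
  n <- length(ch$patient_id)
  if (is.null(weights)) {
    weights <- as.integer(!(ch$patient_id %in% exclude_patient_ids))
  } else {
    if (length(weights) != n || any(weights < 0) || any(weights != round(weights)))
      stop("`weights` must be non-negative integers, one per patient", call. = FALSE)
    weights <- as.integer(weights)
  }
  refs <- vector("list", length(CLASS_LEVELS))
  names(refs) <- CLASS_LEVELS
  for (cl in CLASS_LEVELS) {
    use <- ch$true_class == cl & weights > 0L
    if (!any(use))
      stop(sprintf("class %s has no patients left after exclusion", cl),
           call. = FALSE)
    w <- weights[use]
    sums <- as.vector(ch$counts[, use, drop = FALSE] %*% w)
    total <- sum(ch$total[use] * w)
    refs[[cl]] <- new_reference(cl, ch$scheme, sums, total, alpha,
                                ch$patient_id[use])
  }
  refs
}
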