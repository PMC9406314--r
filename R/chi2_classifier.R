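# Chi-squared discrepancy classifier.
#
# T_t(i) = sum_m (O_m(i) - E_{t,m})^2 / E_{t,m}, with E_{t,m} = N(i) p_{t,m}.
# The statistic is used purely as a discrepancy score between one patient's
# histogram and each class reference; the class with the smallest score is
# assigned. No degrees-of-freedom calibration or p-value is attached.

#' Chi-squared discrepancy between a patient histogram and a reference
#'
#' Bins where both the observed and the expected count are zero contribute
#' nothing; a bin with zero expected count but nonzero observed count makes
#' the statistic `+Inf` (only possible under `alpha = 0` smoothing).
#'
#' @param histogram An `adc_histogram`.
#' @param ref An `adc_reference` sharing the same binning scheme.
#' @return A single non-negative number (possibly `Inf`).
#' @export
#' @examples
#' sch <- binning_scheme(n_bins = 2)
#' h <- adc_histogram("p1", c(rep(50, 3), rep(150, 7)), sch)
#' r <- fit_reference(list(adc_histogram("q", c(rep(50, 5), rep(150, 5)), sch)),
#'                    alpha = 0)
#' chi2_statistic(h, r)  # (3-5)^2/5 + (7-5)^2/5 = 1.6
chi2_statistic <- function(histogram, ref) {
  stopifnot(inherits(histogram, "adc_histogram"), inherits(ref, "adc_reference"))
  if (!same_scheme(histogram$scheme, ref$scheme))
    stop("histogram and reference use different binning schemes", call. = FALSE)
  O <- histogram$counts
  E <- as.numeric(histogram$total) * ref$probs
  chi2_terms_sum(O, E)
}

chi2_terms_sum <- function(O, E) {
  zero <- E == 0
  if (any(zero & O > 0)) return(Inf)
  keep <- !zero
  sum((O[keep] - E[keep])^2 / E[keep])
}

#' Classify one patient by minimum chi-squared discrepancy
#'
#' Computes `T_t(i)` against each candidate class reference and predicts the
#' argmin. Exact ties are broken by the fixed class order PA < WT < MT and
#' flagged; two infinite statistics also tie.
#'
#' @param histogram An `adc_histogram`.
#' @param refs Named list of `adc_reference` covering every candidate class.
#' @param candidate_classes Subset of `c("PA","WT","MT")` of size >= 2.
#'   Pairwise comparisons (e.g. MT versus WT) restrict this to the named
#'   pair; three-way classification uses all three.
#' @return A `chi2_classification`: `patient_id`, `statistics` (named, one
#'   per candidate), `predicted_class`, `candidate_classes`, `tie_flag`.
#' @export
classify_chi2 <- function(histogram, refs,
                          candidate_classes = CLASS_LEVELS) {
  candidate_classes <- CLASS_LEVELS[CLASS_LEVELS %in% candidate_classes]
  if (length(candidate_classes) < 2L)
    stop("at least two candidate classes are required", call. = FALSE)
  if (!all(candidate_classes %in% names(refs)))
    stop("`refs` must contain a reference for every candidate class", call. = FALSE)
  stats <- vapply(candidate_classes,
                  function(cl) chi2_statistic(histogram, refs[[cl]]),
                  numeric(1))
  best <- min(stats)
  hit <- stats == best  # Inf == Inf is TRUE: all-infinite statistics tie
  structure(
    list(patient_id = histogram$patient_id, statistics = stats,
         predicted_class = candidate_classes[which(hit)[1L]],
         candidate_classes = candidate_classes,
         tie_flag = sum(hit) > 1L),
    class = "chi2_classification"
  )
}

#' @export
print.chi2_classification <- function(x, ...) {
  cat(sprintf("Patient %s -> %s%s  [%s]\n", x$patient_id, x$predicted_class,
              if (x$tie_flag) " (tie)" else "",
              paste(sprintf("%s: %.4g", names(x$statistics), x$statistics),
                    collapse = ", ")))
  invisible(x)
}

# Vectorized three-way (or pairwise) prediction over the columns of a
# cohort_histograms object; the hot path of the resampling engines.
# Returns a character vector of predicted classes.
predict_chi2 <- function(ch, refs, idx = seq_along(ch$patient_id),
                         candidate_classes = CLASS_LEVELS) {
  candidate_classes <- CLASS_LEVELS[CLASS_LEVELS %in% candidate_classes]
  O <- ch$counts[, idx, drop = FALSE]
  N <- ch$total[idx]
  T <- matrix(NA_real_, nrow = length(candidate_classes), ncol = length(idx))
  for (r in seq_along(candidate_classes)) {
    p <- refs[[candidate_classes[r]]]$probs
    if (all(p > 0)) {
      E <- outer(p, N)
      T[r, ] <- colSums((O - E)^2 / E)
    } else {
      T[r, ] <- vapply(seq_along(idx), function(j)
        chi2_terms_sum(O[, j], N[j] * p), numeric(1))
    }
  }
  candidate_classes[apply(T, 2L, which.min)]
}
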