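# Fixed-width binning of voxel-level ADC values.
#
# All ADC values in this package are on the 1e-6 mm^2/s scale, so the
# conventional "intervals of 100" bin width is literally 100 in these units.

CLASS_LEVELS <- c("PA", "WT", "MT")

#' Define a fixed-width ADC binning scheme
#'
#' Bin `m` (zero-based) covers the half-open interval
#' `[origin + m*width, origin + (m+1)*width)`; a value equal to a bin
#' boundary falls in the right-hand bin. The same scheme must be shared by
#' every histogram that enters a pooled reference distribution.
#'
#' @param origin Left edge of the first bin, in 1e-6 mm^2/s. Default 0.
#' @param width Bin width, in 1e-6 mm^2/s, strictly positive. Default 100.
#' @param n_bins Number of bins. The default 40 covers 0-4000, which spans
#'   free-water diffusion (~3000) with margin.
#' @return An object of class `binning_scheme`.
#' @export
#' @examples
#' sch <- binning_scheme()
#' bin_edges(sch)[1:5]
binning_scheme <- function(origin = 0, width = 100, n_bins = 40) {
  if (!is.numeric(origin) || length(origin) != 1L || !is.finite(origin))
    stop("`origin` must be a single finite number", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || !is.finite(width) || width <= 0)
    stop("`width` must be a single positive number", call. = FALSE)
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins < 1 || n_bins != round(n_bins))
    stop("`n_bins` must be a positive integer", call. = FALSE)
  structure(
    list(origin = as.numeric(origin), width = as.numeric(width),
         n_bins = as.integer(n_bins)),
    class = "binning_scheme"
  )
}

#' Bin edges of a binning scheme
#'
#' @param scheme A [binning_scheme()].
#' @return Numeric vector of length `n_bins + 1` with all bin edges.
#' @export
bin_edges <- function(scheme) {
  stopifnot(inherits(scheme, "binning_scheme"))
  scheme$origin + scheme$width * (0:scheme$n_bins)
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("ADC binning scheme: %d bins of width %g starting at %g (units 1e-6 mm^2/s)\n",
              x$n_bins, x$width, x$origin))
  invisible(x)
}

same_scheme <- function(a, b) {
  isTRUE(all.equal(a$origin, b$origin)) &&
    isTRUE(all.equal(a$width, b$width)) &&
    a$n_bins == b$n_bins
}

#' Bin ADC values into fixed-width histogram counts
#'
#' Each value is assigned to the unique half-open bin `[left, right)`
#' containing it. Values at or above the upper edge of the last bin are
#' handled per `overflow`: `"clamp"` places them in the last bin with a
#' warning (rare hot voxels should not abort a pipeline), `"error"` rejects
#' the input (useful to catch fixture mistakes).
#'
#' @param values Numeric vector of ADC values, non-empty, all finite and
#'   `>= origin`.
#' @param scheme A [binning_scheme()].
#' @param overflow One of `"clamp"` (default) or `"error"`.
#' @return Integer vector of counts of length `scheme$n_bins`; the counts
#'   always sum to `length(values)`.
#' @export
#' @examples
#' bin_values(c(50, 100, 199.9, 250), binning_scheme(n_bins = 5))
bin_values <- function(values, scheme, overflow = c("clamp", "error")) {
  overflow <- match.arg(overflow)
  stopifnot(inherits(scheme, "binning_scheme"))
  if (length(values) == 0L)
    stop("`values` must be non-empty", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("all ADC values must be finite numbers", call. = FALSE)
  if (any(values < scheme$origin))
    stop("ADC value below the binning origin", call. = FALSE)
  idx <- floor((values - scheme$origin) / scheme$width)
  over <- idx >= scheme$n_bins
  if (any(over)) {
    if (overflow == "error")
      stop(sprintf("%d value(s) at or above the upper histogram edge", sum(over)),
           call. = FALSE)
    warning(sprintf("%d value(s) at or above the upper histogram edge clamped to the last bin",
                    sum(over)), call. = FALSE)
    idx[over] <- scheme$n_bins - 1L
  }
  tabulate(as.integer(idx) + 1L, nbins = scheme$n_bins)
}

#' Build a patient histogram
#'
#' @param patient_id Patient identifier (single string).
#' @param values Voxel-level ADC values (see [bin_values()]).
#' @param scheme A [binning_scheme()].
#' @param overflow Overflow policy passed to [bin_values()].
#' @return An `adc_histogram`: list with `patient_id`, `scheme`, `counts`
#'   (length `n_bins`) and `total` (`= length(values)`).
#' @export
adc_histogram <- function(patient_id, values, scheme = binning_scheme(),
                          overflow = c("clamp", "error")) {
  counts <- bin_values(values, scheme, overflow)
  structure(
    list(patient_id = as.character(patient_id), scheme = scheme,
         counts = counts, total = length(values)),
    class = "adc_histogram"
  )
}

#' Mean ADC of one patient
#'
#' The whole-lesion mean, the conventional single-number ADC summary used by
#' the threshold comparator.
#'
#' @param values Non-empty numeric vector of voxel ADC values.
#' @return The arithmetic mean.
#' @export
patient_mean <- function(values) {
  if (length(values) == 0L)
    stop("`values` must be non-empty", call. = FALSE)
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("all ADC values must be finite numbers", call. = FALSE)
  mean(values)
}

#' Bin an entire cohort under one shared scheme
#'
#' Produces the compact representation the classifiers and the resampling
#' engines operate on: one counts matrix (bins x patients) plus per-patient
#' metadata.
#'
#' @param cohort An `adc_cohort` (see [read_cohort_manifest()] or
#'   [generate_cohort()]).
#' @param scheme A [binning_scheme()] shared by all patients.
#' @param overflow Overflow policy passed to [bin_values()].
#' @return A `cohort_histograms` object: `scheme`, `counts` (integer matrix,
#'   `n_bins` rows, one column per patient), `patient_id`, `true_class`,
#'   `total` (voxel counts) and `mean_adc`.
#' @export
cohort_histograms <- function(cohort, scheme = binning_scheme(),
                              overflow = c("clamp", "error")) {
  stopifnot(inherits(cohort, "adc_cohort"))
  overflow <- match.arg(overflow)
  n <- length(cohort$samples)
  counts <- matrix(0L, nrow = scheme$n_bins, ncol = n)
  total <- integer(n)
  mean_adc <- numeric(n)
  for (j in seq_len(n)) {
    s <- cohort$samples[[j]]
    counts[, j] <- bin_values(s$voxels, scheme, overflow)
    total[j] <- length(s$voxels)
    mean_adc[j] <- patient_mean(s$voxels)
  }
  structure(
    list(scheme = scheme, counts = counts,
         patient_id = vapply(cohort$samples, `[[`, character(1), "patient_id"),
         true_class = vapply(cohort$samples, `[[`, character(1), "true_class"),
         total = total, mean_adc = mean_adc),
    class = "cohort_histograms"
  )
}

#' @export
print.cohort_histograms <- function(x, ...) {
  tab <- table(factor(x$true_class, levels = CLASS_LEVELS))
  cat(sprintf("Binned cohort: %d patients (%s), %d bins, %d voxels\n",
              length(x$patient_id),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              x$scheme$n_bins, sum(x$total)))
  invisible(x)
}

# Extract one patient's adc_histogram from a cohort_histograms object.
histogram_of <- function(ch, j) {
  structure(
    list(patient_id = ch$patient_id[j], scheme = ch$scheme,
         counts = ch$counts[, j], total = ch$total[j]),
    class = "adc_histogram"
  )
}
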