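# Synthetic ADC cohort generator.
#
# Class-conditional voxel distributions are finite mixtures of
# truncated-at-zero normal components. The mixture form mirrors the tissue
# interpretation of histogram skew: malignant lesions are mostly densely
# cellular (low ADC) with a minority of necrotic voxels (high ADC), giving
# right skew; pleomorphic adenomas are the reverse, giving left skew;
# Warthin tumors sit low with a single compact mode. The numeric defaults
# are this package's own choices — a well-separated "textbook" cohort — and
# are plain configuration, not literature values.

#' Construct a class-conditional voxel generator spec
#'
#' @param tumor_class `"PA"`, `"WT"` or `"MT"`.
#' @param weights Positive mixture weights; normalized to sum to 1.
#' @param locations Component means on the ADC scale (1e-6 mm^2/s).
#' @param scales Positive component standard deviations.
#' @return A `class_generator_spec`.
#' @export
class_generator_spec <- function(tumor_class, weights, locations, scales) {
  stopifnot(tumor_class %in% CLASS_LEVELS)
  k <- length(weights)
  if (k == 0L || length(locations) != k || length(scales) != k)
    stop("weights, locations and scales must be non-empty and parallel",
         call. = FALSE)
  if (any(weights <= 0) || any(scales <= 0))
    stop("weights and scales must be strictly positive", call. = FALSE)
  structure(
    list(tumor_class = tumor_class,
         weights = weights / sum(weights),
         locations = as.numeric(locations),
         scales = as.numeric(scales)),
    class = "class_generator_spec"
  )
}

#' Default class generator specs
#'
#' WT: one low compact component. PA: high dominant component with a lower
#' minority shoulder (left skew). MT: low dominant component with a high
#' necrotic minority (right skew). Mixture means order WT < MT < PA.
#'
#' @return Named list `list(PA = , WT = , MT = )` of
#'   [class_generator_spec()] objects.
#' @export
default_class_specs <- function() {
  list(
    PA = class_generator_spec("PA", c(0.85, 0.15), c(1950, 1250), c(200, 250)),
    WT = class_generator_spec("WT", 1, 850, 120),
    MT = class_generator_spec("MT", c(0.80, 0.20), c(950, 1900), c(150, 300))
  )
}

#' Closed-form mixture moments of a generator spec
#'
#' Mean, variance and third central moment of the (untruncated) normal
#' mixture; with the default parameters the mass below zero is negligible
#' (< 1e-10), so these serve as analytic targets for Monte Carlo checks.
#'
#' @param spec A [class_generator_spec()].
#' @return Named vector `c(mean = , var = , m3 = )`; `m3 > 0` means right
#'   skew.
#' @export
mixture_moments <- function(spec) {
  w <- spec$weights; mu <- spec$locations; s <- spec$scales
  m <- sum(w * mu)
  d <- mu - m
  c(mean = m,
    var = sum(w * (s^2 + d^2)),
    m3 = sum(w * (d^3 + 3 * d * s^2)))
}

#' Cohort generator configuration
#'
#' @param n_per_class Named integer vector of patients per class; the
#'   default `c(PA = 30, WT = 22, MT = 21)` reproduces the composition of
#'   a 73-patient parotid tumor cohort.
#' @param voxel_count_range Integer interval for per-patient voxel counts.
#'   The default lower bound 50 corresponds to a 1 cm^3 lesion at a
#'   2 x 2 x 5 mm voxel size (20 mm^3/voxel), the usual minimal lesion
#'   volume for whole-lesion ADC work; 5000 covers large tumors.
#' @param seed Integer RNG seed.
#' @param class_specs Named list of [class_generator_spec()] per class.
#' @param overlap_factor Number in \[0, 1\] mixing each class spec toward
#'   the prevalence-weighted grand mixture: 0 leaves the specs untouched,
#'   1 makes all three classes draw from the identical grand mixture
#'   (chance-level stress test); intermediate values shrink class mean
#'   differences and inflate within-class spread.
#' @return A `cohort_generator_config`.
#' @export
cohort_generator_config <- function(n_per_class = c(PA = 30, WT = 22, MT = 21),
                                    voxel_count_range = c(50, 5000),
                                    seed = 1,
                                    class_specs = default_class_specs(),
                                    overlap_factor = 0) {
  if (!all(CLASS_LEVELS %in% names(n_per_class)) || any(n_per_class < 0))
    stop("`n_per_class` must name PA, WT and MT with non-negative counts",
         call. = FALSE)
  if (length(voxel_count_range) != 2L || voxel_count_range[1] < 1 ||
      voxel_count_range[1] > voxel_count_range[2])
    stop("invalid `voxel_count_range`", call. = FALSE)
  if (!all(CLASS_LEVELS %in% names(class_specs)))
    stop("`class_specs` must name PA, WT and MT", call. = FALSE)
  if (overlap_factor < 0 || overlap_factor > 1)
    stop("`overlap_factor` must lie in [0, 1]", call. = FALSE)
  specs <- apply_overlap(class_specs[CLASS_LEVELS],
                         n_per_class[CLASS_LEVELS], overlap_factor)
  structure(
    list(n_per_class = n_per_class[CLASS_LEVELS],
         voxel_count_range = as.integer(voxel_count_range),
         seed = as.integer(seed),
         class_specs = specs,
         overlap_factor = overlap_factor),
    class = "cohort_generator_config"
  )
}

# Mix each class spec with the prevalence-weighted grand mixture:
# spec_f = (1-f) * own + f * grand. At f = 1 every class is exactly the
# grand mixture, so class-conditional distributions coincide.
apply_overlap <- function(specs, n_per_class, f) {
  if (f == 0) return(specs)
  prev <- n_per_class / sum(n_per_class)
  grand <- list(
    weights = unlist(lapply(CLASS_LEVELS,
                            function(cl) prev[[cl]] * specs[[cl]]$weights)),
    locations = unlist(lapply(specs, `[[`, "locations")),
    scales = unlist(lapply(specs, `[[`, "scales")))
  lapply(specs, function(sp) {
    w <- c((1 - f) * sp$weights, f * grand$weights)
    loc <- c(sp$locations, grand$locations)
    sc <- c(sp$scales, grand$scales)
    keep <- w > 0
    class_generator_spec(sp$tumor_class, w[keep], loc[keep], sc[keep])
  })
}

# Draw n voxels from a truncated-at-zero normal mixture.
draw_mixture <- function(n, spec) {
  comp <- sample.int(length(spec$weights), n, replace = TRUE,
                     prob = spec$weights)
  v <- stats::rnorm(n, spec$locations[comp], spec$scales[comp])
  while (any(v < 0)) {        # truncation at zero by redrawing
    neg <- which(v < 0)
    v[neg] <- stats::rnorm(length(neg), spec$locations[comp[neg]],
                           spec$scales[comp[neg]])
  }
  v
}

#' Generate a reproducible synthetic cohort
#'
#' For each class, `n_per_class` patients are created; each patient's voxel
#' count is drawn uniformly from `voxel_count_range` and voxels are drawn
#' i.i.d. from the class mixture (no spatial correlation — the downstream
#' analysis is purely histogram-based). Identical seeds give identical
#' cohorts.
#'
#' @param config A [cohort_generator_config()].
#' @return An `adc_cohort` with patients ordered PA, WT, MT and ids like
#'   `"PA01"`.
#' @export
generate_cohort <- function(config = cohort_generator_config()) {
  stopifnot(inherits(config, "cohort_generator_config"))
  set.seed(config$seed)
  samples <- list()
  for (cl in CLASS_LEVELS) {
    n_cl <- config$n_per_class[[cl]]
    if (n_cl == 0) next
    spec <- config$class_specs[[cl]]
    lo <- config$voxel_count_range[1]; hi <- config$voxel_count_range[2]
    for (i in seq_len(n_cl)) {
      n_vox <- if (lo == hi) lo else lo + sample.int(hi - lo + 1L, 1L) - 1L
      samples[[length(samples) + 1L]] <- patient_sample(
        sprintf("%s%02d", cl, i), cl, draw_mixture(n_vox, spec))
    }
  }
  new_cohort(samples)
}

#' Embed a patient's voxels in a synthetic ADC map with a VOI mask
#'
#' Builds an ellipsoidal volume-of-interest in the center of the grid,
#' trimmed deterministically (outermost voxels first, row-major index as
#' tie-break) to exactly the patient's voxel count, writes the patient's
#' voxel values at the mask positions in row-major order, and fills the
#' background with parenchyma-like values (normal, mean 1100, sd 150,
#' truncated at zero). Extraction with [extract_voxels_from_mask()]
#' recovers the patient's voxel values exactly.
#'
#' @param patient A `patient_sample`.
#' @param grid_shape Integer vector of 3 array dimensions; must be able to
#'   hold the patient's voxels inside the inscribed ellipsoid.
#' @param seed Integer seed for the background texture.
#' @return List with `adc_map` and `voi_mask`, both 3-D arrays of
#'   `grid_shape` dimensions; the mask is 0/1 with exactly
#'   `length(patient$voxels)` ones.
#' @export
generate_map_and_mask <- function(patient, grid_shape = c(32, 32, 16),
                                  seed = 1) {
  stopifnot(inherits(patient, "patient_sample"), length(grid_shape) == 3L)
  n_vox <- length(patient$voxels)
  dims <- as.integer(grid_shape)
  center <- (dims + 1) / 2
  semi <- dims / 2
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                   z = seq_len(dims[3]))
  r2 <- ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2
  inside <- which(r2 <= 1)
  if (length(inside) < n_vox)
    stop(sprintf("grid %s too small for %d voxels (%d fit in the ellipsoid)",
                 paste(dims, collapse = "x"), n_vox, length(inside)),
         call. = FALSE)
  # column-major linear index of grid points; row-major rank for tie-break
  lin <- g$x + dims[1] * (g$y - 1L) + dims[1] * dims[2] * (g$z - 1L)
  rowmajor <- g$z + dims[3] * (g$y - 1L) + dims[3] * dims[2] * (g$x - 1L)
  keep <- inside[order(r2[inside], rowmajor[inside])][seq_len(n_vox)]
  mask <- array(0, dim = dims)
  mask[lin[keep]] <- 1
  set.seed(seed)
  bg <- stats::rnorm(prod(dims), 1100, 150)
  while (any(bg < 0)) bg[bg < 0] <- stats::rnorm(sum(bg < 0), 1100, 150)
  adc_map <- array(bg, dim = dims)
  # place voxels so that row-major extraction returns them in order
  keep_rm <- keep[order(rowmajor[keep])]
  adc_map[lin[keep_rm]] <- patient$voxels
  list(adc_map = adc_map, voi_mask = mask)
}
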