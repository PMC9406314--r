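# On-disk representations: cohort manifests (JSON), per-patient voxel
# tables (CSV, one value per row), ADC map + VOI mask pairs (NIfTI),
# histogram tables (TSV), fitted references and metric reports (JSON).
#
# ADC values are standardized internally to 1e-6 mm^2/s; a manifest may
# declare "1e-3 mm^2/s" and its voxel values are converted on read.

#' Construct a validated patient sample
#'
#' @param patient_id Single string, unique within a cohort.
#' @param true_class One of `"PA"`, `"WT"`, `"MT"`.
#' @param voxels Non-empty numeric vector of finite, non-negative ADC
#'   values in 1e-6 mm^2/s.
#' @return A `patient_sample`.
#' @export
patient_sample <- function(patient_id, true_class, voxels) {
  if (!is.character(patient_id) || length(patient_id) != 1L || !nzchar(patient_id))
    stop("`patient_id` must be a single non-empty string", call. = FALSE)
  if (!(true_class %in% CLASS_LEVELS))
    stop(sprintf("unknown class label '%s' (expected PA, WT or MT)", true_class),
         call. = FALSE)
  if (length(voxels) == 0L)
    stop(sprintf("patient %s has an empty voxel list", patient_id), call. = FALSE)
  if (!is.numeric(voxels) || any(!is.finite(voxels)) || any(voxels < 0))
    stop(sprintf("patient %s has non-finite or negative voxel values", patient_id),
         call. = FALSE)
  structure(
    list(patient_id = patient_id, true_class = true_class,
         voxels = as.numeric(voxels)),
    class = "patient_sample"
  )
}

new_cohort <- function(samples) {
  ids <- vapply(samples, `[[`, character(1), "patient_id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate patient_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  classes <- vapply(samples, `[[`, character(1), "true_class")
  counts <- table(factor(classes, levels = CLASS_LEVELS))
  structure(
    list(samples = samples,
         class_counts = stats::setNames(as.integer(counts), CLASS_LEVELS)),
    class = "adc_cohort"
  )
}

#' @export
print.adc_cohort <- function(x, ...) {
  cat(sprintf("ADC cohort: %d patients (%s)\n", length(x$samples),
              paste(sprintf("%s %d", names(x$class_counts), x$class_counts),
                    collapse = ", ")))
  invisible(x)
}

unit_factor <- function(units) {
  switch(units,
         "1e-6 mm^2/s" = 1,
         "1e-3 mm^2/s" = 1000,
         stop(sprintf("unsupported ADC units '%s'", units), call. = FALSE))
}

#' Read a cohort manifest
#'
#' The manifest is one JSON document:
#' \preformatted{
#' {"units": "1e-6 mm^2/s",
#'  "patients": [
#'    {"patient_id": "PA01", "true_class": "PA", "voxels": [1900, 2050]},
#'    {"patient_id": "WT01", "true_class": "WT", "voxel_file": "WT01.csv"},
#'    {"patient_id": "MT01", "true_class": "MT",
#'     "adc_map": "MT01_adc.nii.gz", "voi_mask": "MT01_mask.nii.gz"}]}
#' }
#' Each patient record names exactly one voxel source: inline `voxels`, a
#' one-column `voxel_file` CSV, or an `adc_map` + `voi_mask` NIfTI pair.
#' Relative paths are resolved against the manifest's directory. `units`
#' is optional and defaults to `"1e-6 mm^2/s"`; values in
#' `"1e-3 mm^2/s"` are converted.
#'
#' @param path Path to the manifest JSON file.
#' @return An `adc_cohort`.
#' @export
read_cohort_manifest <- function(path) {
  if (!file.exists(path))
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$patients) || length(doc$patients) == 0L)
    stop("manifest lists no patients", call. = FALSE)
  fac <- unit_factor(if (is.null(doc$units)) "1e-6 mm^2/s" else doc$units)
  base <- dirname(path)
  resolve <- function(p) if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
  samples <- lapply(doc$patients, function(rec) {
    if (is.null(rec$patient_id) || is.null(rec$true_class))
      stop("patient record lacks patient_id or true_class", call. = FALSE)
    voxels <-
      if (!is.null(rec$voxels)) {
        unlist(rec$voxels)
      } else if (!is.null(rec$voxel_file)) {
        read_voxel_csv(resolve(rec$voxel_file))
      } else if (!is.null(rec$adc_map) && !is.null(rec$voi_mask)) {
        extract_voxels_from_mask(read_nifti_array(resolve(rec$adc_map)),
                                 read_nifti_array(resolve(rec$voi_mask)))
      } else {
        stop(sprintf("patient %s has no voxel source", rec$patient_id),
             call. = FALSE)
      }
    patient_sample(rec$patient_id, rec$true_class, voxels * fac)
  })
  new_cohort(samples)
}

#' Write a cohort to a manifest plus per-patient CSV files
#'
#' @param cohort An `adc_cohort`.
#' @param dir Output directory (created if missing).
#' @param inline If `TRUE`, voxel values are embedded in the manifest
#'   instead of per-patient CSV files.
#' @return The manifest path, invisibly.
#' @export
write_cohort_manifest <- function(cohort, dir, inline = FALSE) {
  stopifnot(inherits(cohort, "adc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  patients <- lapply(cohort$samples, function(s) {
    if (inline) {
      list(patient_id = s$patient_id, true_class = s$true_class,
           voxels = s$voxels)
    } else {
      f <- paste0(s$patient_id, ".csv")
      write_voxel_csv(s$voxels, file.path(dir, f))
      list(patient_id = s$patient_id, true_class = s$true_class,
           voxel_file = f)
    }
  })
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(units = "1e-6 mm^2/s", patients = patients),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read/write a one-column voxel CSV (one ADC value per row)
#'
#' @param path File path.
#' @return `read_voxel_csv` returns a numeric vector.
#' @export
read_voxel_csv <- function(path) {
  if (!file.exists(path))
    stop(sprintf("voxel file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && is.na(suppressWarnings(as.numeric(lines[1L]))))
    lines <- lines[-1L]  # tolerate a header row
  v <- suppressWarnings(as.numeric(lines))
  if (length(v) == 0L || any(is.na(v)))
    stop(sprintf("voxel file %s is not a one-column numeric table", path),
         call. = FALSE)
  v
}

#' @rdname read_voxel_csv
#' @param values Numeric vector to write.
#' @export
write_voxel_csv <- function(values, path) {
  writeLines(c("adc", format(values, digits = 17, trim = TRUE,
                             scientific = FALSE)), path)
  invisible(path)
}

# Read a NIfTI file as a plain numeric array.
read_nifti_array <- function(path) {
  if (!file.exists(path))
    stop(sprintf("NIfTI file not found: %s", path), call. = FALSE)
  arr <- as.array(RNifti::readNifti(path))
  storage.mode(arr) <- "double"
  arr
}

#' Write a 3-D array as NIfTI
#'
#' @param arr Numeric 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_nifti_array <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Extract whole-lesion voxel values from an ADC map and a VOI mask
#'
#' Returns the ADC values at the nonzero mask positions, traversed in
#' row-major order (last array index fastest). The histogram downstream is
#' order-invariant; the fixed order only makes serialized intermediates
#' reproducible.
#'
#' @param adc_map 3-D numeric array of ADC values.
#' @param mask 3-D array of the same dimensions containing only 0 and 1.
#' @return Numeric vector of length `sum(mask)`.
#' @export
extract_voxels_from_mask <- function(adc_map, mask) {
  if (!identical(dim(adc_map), dim(mask)))
    stop("ADC map and mask dimensions differ", call. = FALSE)
  if (!all(mask %in% c(0, 1)))
    stop("mask must contain only 0 and 1", call. = FALSE)
  if (sum(mask) == 0)
    stop("mask selects no voxels", call. = FALSE)
  perm <- rev(seq_along(dim(adc_map)))
  m <- aperm(adc_map, perm)
  k <- aperm(mask, perm)
  as.numeric(m[k == 1])
}

#' Write/read a histogram TSV (bin_left_edge, bin_right_edge, count)
#'
#' @param histogram An `adc_histogram`.
#' @param path File path.
#' @export
write_histogram_tsv <- function(histogram, path) {
  stopifnot(inherits(histogram, "adc_histogram"))
  edges <- bin_edges(histogram$scheme)
  df <- data.frame(bin_left_edge = edges[-length(edges)],
                   bin_right_edge = edges[-1L],
                   count = histogram$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram_tsv
#' @param patient_id Id to attach to the histogram read back.
#' @export
read_histogram_tsv <- function(path, patient_id = NA_character_) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("bin_left_edge", "bin_right_edge", "count") %in% names(df)))
  width <- df$bin_right_edge[1L] - df$bin_left_edge[1L]
  scheme <- binning_scheme(origin = df$bin_left_edge[1L], width = width,
                           n_bins = nrow(df))
  structure(
    list(patient_id = patient_id, scheme = scheme,
         counts = as.integer(df$count), total = sum(df$count)),
    class = "adc_histogram"
  )
}

#' Serialize fitted references to JSON and back
#'
#' @param refs Named list of `adc_reference` (as from
#'   [fit_all_references()]).
#' @param path File path.
#' @export
write_references <- function(refs, path) {
  out <- lapply(refs, function(r) list(
    tumor_class = r$tumor_class,
    scheme = r$scheme[c("origin", "width", "n_bins")],
    alpha = r$alpha,
    probs = r$probs,
    source_patient_ids = r$source_patient_ids))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_references
#' @export
read_references <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  lapply(doc, function(r) {
    structure(
      list(tumor_class = r$tumor_class,
           scheme = binning_scheme(r$scheme$origin, r$scheme$width,
                                   r$scheme$n_bins),
           probs = as.numeric(r$probs),
           alpha = r$alpha,
           source_patient_ids = as.character(r$source_patient_ids)),
      class = "adc_reference")
  })
}

#' Write a metrics report to JSON (deterministic serialization)
#'
#' Key order and number formatting are fixed, so two writes of the same
#' report are byte-identical; undefined metrics (e.g. the precision of a
#' class never predicted) are serialized as `null`, never omitted and
#' never coerced to 0.
#'
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  cm <- lapply(stats::setNames(nm = CLASS_LEVELS), function(t)
    as.list(report$confusion[t, ]))
  out <- list(
    scheme = report$scheme,
    n_evaluated = report$n_evaluated,
    confusion = cm,
    total_accuracy = report$total_accuracy,
    precision = as.list(report$precision),
    tpr = as.list(report$tpr),
    pairwise_sens_spec = lapply(report$pairwise_sens_spec, as.list),
    diagnostics = report$diagnostics,
    config = report$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @return `read_report` returns the `metrics_report` re-assembled from
#'   disk.
#' @export
read_report <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cm <- matrix(0L, 3L, 3L,
               dimnames = list(true = CLASS_LEVELS, predicted = CLASS_LEVELS))
  for (t in CLASS_LEVELS)
    for (p in CLASS_LEVELS)
      cm[t, p] <- as.integer(doc$confusion[[t]][[p]])
  num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  vec <- function(lst) vapply(lst, num, numeric(1))
  structure(
    list(scheme = doc$scheme,
         n_evaluated = as.integer(doc$n_evaluated),
         confusion = cm,
         total_accuracy = num(doc$total_accuracy),
         precision = vec(doc$precision),
         tpr = vec(doc$tpr),
         pairwise_sens_spec = lapply(doc$pairwise_sens_spec, vec),
         diagnostics = lapply(doc$diagnostics, function(x) x),
         config = doc$config),
    class = "metrics_report"
  )
}
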