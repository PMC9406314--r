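test_that("manifest with inline voxels parses into a validated cohort", {
  dir <- withr::local_tempdir()
  manifest <- file.path(dir, "manifest.json")
  writeLines('{
    "patients": [
      {"patient_id": "a", "true_class": "PA", "voxels": [1900, 2000, 2100]},
      {"patient_id": "b", "true_class": "MT", "voxels": [950, 1000]}
    ]}', manifest)
  coh <- read_cohort_manifest(manifest)
  expect_length(coh$samples, 2)
  expect_equal(coh$class_counts, c(PA = 1L, WT = 0L, MT = 1L))
  expect_equal(coh$samples[[1]]$voxels, c(1900, 2000, 2100))
})

test_that("manifest validation rejects duplicates, bad labels and empty voxels", {
  dir <- withr::local_tempdir()
  m <- file.path(dir, "m.json")
  writeLines('{"patients": [
    {"patient_id": "a", "true_class": "PA", "voxels": [1]},
    {"patient_id": "a", "true_class": "WT", "voxels": [2]}]}', m)
  expect_error(read_cohort_manifest(m), "duplicate patient_id")
  writeLines('{"patients": [
    {"patient_id": "a", "true_class": "XX", "voxels": [1]}]}', m)
  expect_error(read_cohort_manifest(m), "unknown class label")
  writeLines('{"patients": [
    {"patient_id": "a", "true_class": "PA", "voxels": []}]}', m)
  expect_error(read_cohort_manifest(m), "empty voxel list")
  expect_error(read_cohort_manifest(file.path(dir, "absent.json")), "not found")
})

test_that("per-patient voxel CSVs round-trip through the manifest", {
  dir <- withr::local_tempdir()
  set.seed(1)
  vox <- round(runif(50, 400, 2800), 3)
  write_voxel_csv(vox, file.path(dir, "p.csv"))
  writeLines('{"patients": [
    {"patient_id": "p", "true_class": "WT", "voxel_file": "p.csv"}]}',
    file.path(dir, "m.json"))
  coh <- read_cohort_manifest(file.path(dir, "m.json"))
  expect_length(coh$samples[[1]]$voxels, 50)
  expect_equal(coh$samples[[1]]$voxels, vox)
})

test_that("a manifest declaring 1e-3 mm^2/s units is converted on read", {
  dir <- withr::local_tempdir()
  m <- file.path(dir, "m.json")
  writeLines('{"units": "1e-3 mm^2/s", "patients": [
    {"patient_id": "a", "true_class": "PA", "voxels": [1.9, 2.05]}]}', m)
  coh <- read_cohort_manifest(m)
  expect_equal(coh$samples[[1]]$voxels, c(1900, 2050))
})

test_that("write_cohort_manifest round-trips a cohort (inline and CSV)", {
  coh <- tiny_cohort()
  for (inline in c(TRUE, FALSE)) {
    dir <- withr::local_tempdir()
    path <- write_cohort_manifest(coh, dir, inline = inline)
    back <- read_cohort_manifest(path)
    expect_equal(back$class_counts, coh$class_counts)
    for (j in seq_along(coh$samples))
      expect_equal(back$samples[[j]]$voxels, coh$samples[[j]]$voxels)
  }
})

test_that("mask extraction returns exactly the masked values", {
  map <- array(1:8, dim = c(2, 2, 2))
  mask <- array(0, dim = c(2, 2, 2))
  mask[map == 3] <- 1; mask[map == 7] <- 1
  expect_setequal(extract_voxels_from_mask(map, mask), c(3, 7))
  full <- array(1, dim = c(2, 2, 2))
  expect_setequal(extract_voxels_from_mask(map, full), 1:8)
  expect_length(extract_voxels_from_mask(map, full), 8)
})

test_that("mask extraction matches a triple-loop oracle, in row-major order", {
  set.seed(5)
  map <- array(runif(500, 0, 3000), dim = c(10, 10, 5))
  mask <- array(rbinom(500, 1, 0.3), dim = c(10, 10, 5))
  mask[1, 1, 1] <- 1  # guarantee non-empty
  oracle <- c()
  for (i in 1:10) for (j in 1:10) for (k in 1:5)
    if (mask[i, j, k] == 1) oracle <- c(oracle, map[i, j, k])
  got <- extract_voxels_from_mask(map, mask)
  expect_length(got, sum(mask))
  expect_identical(got, oracle)  # row-major: last index fastest
})

test_that("mask extraction validates shape, emptiness and binarity", {
  map <- array(1, dim = c(2, 2, 2))
  expect_error(extract_voxels_from_mask(map, array(1, dim = c(2, 2, 3))),
               "dimensions differ")
  expect_error(extract_voxels_from_mask(map, array(0, dim = c(2, 2, 2))),
               "no voxels")
  expect_error(extract_voxels_from_mask(map, array(0.5, dim = c(2, 2, 2))),
               "only 0 and 1")
})

test_that("NIfTI map/mask pairs round-trip through the manifest path", {
  dir <- withr::local_tempdir()
  set.seed(2)
  map <- array(runif(144, 200, 2800), dim = c(6, 6, 4))
  mask <- array(rbinom(144, 1, 0.4), dim = c(6, 6, 4))
  mask[3, 3, 2] <- 1
  write_nifti_array(map, file.path(dir, "adc.nii.gz"))
  write_nifti_array(mask, file.path(dir, "mask.nii.gz"))
  writeLines('{"patients": [
    {"patient_id": "n", "true_class": "MT",
     "adc_map": "adc.nii.gz", "voi_mask": "mask.nii.gz"}]}',
    file.path(dir, "m.json"))
  coh <- read_cohort_manifest(file.path(dir, "m.json"))
  expect_length(coh$samples[[1]]$voxels, sum(mask))
  expect_identical(sort(coh$samples[[1]]$voxels), sort(map[mask == 1]))
})

test_that("histogram TSVs and reference JSON round-trip", {
  dir <- withr::local_tempdir()
  h <- adc_histogram("p1", c(150, 250, 250, 380), binning_scheme(0, 100, 6))
  write_histogram_tsv(h, file.path(dir, "h.tsv"))
  back <- read_histogram_tsv(file.path(dir, "h.tsv"), "p1")
  expect_equal(back$counts, h$counts)
  expect_equal(back$total, h$total)
  expect_true(adchist:::same_scheme(back$scheme, h$scheme))

  ch <- cohort_histograms(tiny_cohort(), binning_scheme(0, 100, 25))
  refs <- fit_all_references(ch, alpha = 0.5)
  write_references(refs, file.path(dir, "refs.json"))
  back <- read_references(file.path(dir, "refs.json"))
  for (cl in c("PA", "WT", "MT")) {
    expect_equal(back[[cl]]$probs, refs[[cl]]$probs)
    expect_equal(back[[cl]]$alpha, 0.5)
    expect_equal(back[[cl]]$source_patient_ids, refs[[cl]]$source_patient_ids)
  }
})

test_that("metric reports serialize deterministically and round-trip", {
  ch <- cohort_histograms(tiny_cohort(), binning_scheme(0, 100, 25))
  rep1 <- loocv(ch, "histogram")
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.json"); f2 <- file.path(dir, "r2.json")
  write_report(rep1, f1)
  write_report(rep1, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical writes
  back <- read_report(f1)
  expect_equal(back$confusion, rep1$confusion)
  expect_equal(back$total_accuracy, rep1$total_accuracy)
  expect_equal(back$precision, rep1$precision)
  expect_equal(back$tpr, rep1$tpr)
  expect_equal(back$pairwise_sens_spec, rep1$pairwise_sens_spec)
})

test_that("a class absent from predictions serializes as null, not omitted", {
  # everyone predicted PA: WT and MT precision undefined
  rep <- adchist:::new_metrics_report(
    true_classes = c("PA", "WT", "MT"),
    predicted_classes = c("PA", "PA", "PA"),
    scheme = "apparent",
    pairwise = list(MT_vs_benign = c(sensitivity = 0, specificity = 1)))
  dir <- withr::local_tempdir()
  write_report(rep, file.path(dir, "r.json"))
  txt <- paste(readLines(file.path(dir, "r.json")), collapse = "")
  expect_match(txt, '"WT":\\s*null')
  expect_match(txt, '"MT":\\s*null')
  back <- read_report(file.path(dir, "r.json"))
  expect_true(is.na(back$precision[["WT"]]))
  expect_true(is.na(back$precision[["MT"]]))
  expect_equal(back$precision[["PA"]], 1 / 3)
})
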