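# Small in-code fixtures shared across test files.

# A 6-patient cohort (2 per class) with cleanly separated, nearly
# single-bin class distributions: WT around 850, MT around 1150, PA
# around 1950 (bin width 100 keeps each class inside 1-2 bins).
tiny_cohort <- function() {
  new_samples <- list(
    patient_sample("PA1", "PA", c(1950, 1960, 1940, 1955)),
    patient_sample("PA2", "PA", c(1945, 1952, 1948)),
    patient_sample("WT1", "WT", c(850, 860, 840)),
    patient_sample("WT2", "WT", c(845, 855, 852, 848)),
    patient_sample("MT1", "MT", c(1150, 1160, 1140)),
    patient_sample("MT2", "MT", c(1145, 1155, 1152))
  )
  structure(list(
    samples = new_samples,
    class_counts = c(PA = 2L, WT = 2L, MT = 2L)
  ), class = "adc_cohort")
}

# Random cohort with the given per-class sizes; voxels uniform on
# class-specific ranges so classes are separable but not degenerate.
random_cohort <- function(n_per_class = c(PA = 4, WT = 3, MT = 3),
                          n_vox = c(20, 60)) {
  ranges <- list(PA = c(1700, 2300), WT = c(600, 1100), MT = c(900, 1600))
  samples <- list()
  for (cl in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cl]])) {
      nv <- sample(n_vox[1]:n_vox[2], 1)
      samples[[length(samples) + 1]] <- patient_sample(
        sprintf("%s%d", cl, i), cl,
        runif(nv, ranges[[cl]][1], ranges[[cl]][2]))
    }
  }
  structure(list(
    samples = samples,
    class_counts = vapply(c(PA = "PA", WT = "WT", MT = "MT"), function(cl)
      sum(vapply(samples, function(s) s$true_class == cl, logical(1))),
      integer(1))
  ), class = "adc_cohort")
}

# Independent brute-force chi-squared discrepancy: explicit per-bin loop.
chi2_loop_oracle <- function(counts, probs, total) {
  acc <- 0
  for (m in seq_along(counts)) {
    E <- total * probs[m]
    O <- counts[m]
    if (E == 0) {
      if (O > 0) return(Inf)
    } else {
      acc <- acc + (O - E)^2 / E
    }
  }
  acc
}

# Independent exhaustive Youden search: every midpoint cut between
# consecutive distinct pooled values plus sentinels, both orientations.
youden_brute_force <- function(pos, neg) {
  v <- sort(unique(c(pos, neg)))
  cuts <- c(v[1] - 1, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2,
            v[length(v)] + 1)
  best <- -Inf
  for (cut in cuts) {
    for (o in c("leq", "geq")) {
      if (o == "leq") J <- mean(pos <= cut) + mean(neg > cut) - 1
      else J <- mean(pos >= cut) + mean(neg < cut) - 1
      if (J > best) best <- J
    }
  }
  best
}
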