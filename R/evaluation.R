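# Confusion matrices, pairwise sensitivity/specificity and the metrics
# report shared by the apparent and cross-validated evaluations.

#' Confusion matrix over the three tumor classes
#'
#' @param true_classes,predicted_classes Equal-length character vectors
#'   with values in `c("PA","WT","MT")`.
#' @return 3x3 integer matrix, rows = true class, columns = predicted
#'   class, in the fixed order PA, WT, MT.
#' @export
confusion <- function(true_classes, predicted_classes) {
  if (length(true_classes) != length(predicted_classes) ||
      length(true_classes) == 0L)
    stop("class vectors must be non-empty and of equal length", call. = FALSE)
  if (!all(true_classes %in% CLASS_LEVELS) ||
      !all(predicted_classes %in% CLASS_LEVELS))
    stop("unknown class label", call. = FALSE)
  tab <- table(factor(true_classes, levels = CLASS_LEVELS),
               factor(predicted_classes, levels = CLASS_LEVELS))
  cm <- matrix(as.integer(tab), nrow = 3L,
               dimnames = list(true = CLASS_LEVELS, predicted = CLASS_LEVELS))
  cm
}

#' Sensitivity and specificity of one binary comparison, MT positive
#'
#' `MT_vs_PA` and `MT_vs_WT` evaluate only the patients of the two named
#' true classes; `MT_vs_benign` evaluates everyone, treating PA and WT
#' jointly as the negative class. Any non-MT prediction counts as a
#' negative call.
#'
#' @param true_classes,predicted_classes Parallel character vectors.
#' @param comparison One of `"MT_vs_benign"`, `"MT_vs_PA"`, `"MT_vs_WT"`.
#' @return Named numeric vector `c(sensitivity = , specificity = )`, both
#'   in \[0, 1\].
#' @export
pairwise_sens_spec <- function(true_classes, predicted_classes,
                               comparison = c("MT_vs_benign", "MT_vs_PA",
                                              "MT_vs_WT")) {
  comparison <- match.arg(comparison)
  stopifnot(length(true_classes) == length(predicted_classes))
  keep <- switch(comparison,
    MT_vs_benign = rep(TRUE, length(true_classes)),
    MT_vs_PA = true_classes %in% c("MT", "PA"),
    MT_vs_WT = true_classes %in% c("MT", "WT"))
  tr <- true_classes[keep]; pr <- predicted_classes[keep]
  pos <- tr == "MT"
  if (!any(pos) || all(pos))
    stop("comparison needs at least one positive and one negative patient",
         call. = FALSE)
  c(sensitivity = mean(pr[pos] == "MT"),
    specificity = mean(pr[!pos] != "MT"))
}

#' Precision and true positive rate of the pooled benign class
#'
#' Merges PA and WT (true and predicted) into one benign class and
#' computes its precision and TPR from the 3x3 confusion matrix.
#'
#' @param cm A 3x3 confusion matrix from [confusion()].
#' @return Named vector `c(precision = , tpr = )`; precision is `NA` when
#'   no patient was predicted benign.
#' @export
pooled_benign_metrics <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 3L))
  benign <- c("PA", "WT")
  tp <- sum(cm[benign, benign])
  pred_benign <- sum(cm[, benign])
  true_benign <- sum(cm[benign, ])
  c(precision = if (pred_benign > 0) tp / pred_benign else NA_real_,
    tpr = tp / true_benign)
}

# Per-class precision / TPR plus the pooled benign row, from a confusion
# matrix. Undefined precisions (class never predicted) are NA, never 0.
class_metrics <- function(cm) {
  prec <- diag(cm) / colSums(cm)
  prec[colSums(cm) == 0] <- NA_real_
  tpr <- diag(cm) / rowSums(cm)
  tpr[rowSums(cm) == 0] <- NA_real_
  pooled <- pooled_benign_metrics(cm)
  list(precision = c(prec, `PA|WT` = unname(pooled["precision"])),
       tpr = c(tpr, `PA|WT` = unname(pooled["tpr"])))
}

# Assemble a metrics_report from pooled truths/predictions.
new_metrics_report <- function(true_classes, predicted_classes, scheme,
                               pairwise = NULL, diagnostics = list(),
                               config = list()) {
  cm <- confusion(true_classes, predicted_classes)
  cmx <- class_metrics(cm)
  if (is.null(pairwise)) {
    pairwise <- lapply(
      stats::setNames(nm = c("MT_vs_benign", "MT_vs_PA", "MT_vs_WT")),
      function(cmp) pairwise_sens_spec(true_classes, predicted_classes, cmp))
  }
  structure(
    list(scheme = scheme,
         n_evaluated = length(true_classes),
         confusion = cm,
         total_accuracy = sum(diag(cm)) / sum(cm),
         precision = cmx$precision,
         tpr = cmx$tpr,
         pairwise_sens_spec = pairwise,
         diagnostics = diagnostics,
         config = config),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Metrics report [%s], %d held-out classifications\n",
              x$scheme, x$n_evaluated))
  cat(sprintf("  total accuracy: %.1f%%\n", 100 * x$total_accuracy))
  cat("  confusion (rows true, cols predicted):\n")
  print(x$confusion)
  fmt <- function(v) paste(sprintf("%s %s", names(v),
                                   ifelse(is.na(v), "--",
                                          sprintf("%.1f%%", 100 * v))),
                           collapse = ", ")
  cat("  precision: ", fmt(x$precision), "\n", sep = "")
  cat("  TPR:       ", fmt(x$tpr), "\n", sep = "")
  for (nm in names(x$pairwise_sens_spec)) {
    p <- x$pairwise_sens_spec[[nm]]
    cat(sprintf("  %-13s sensitivity %.1f%%, specificity %.1f%%\n",
                nm, 100 * p["sensitivity"], 100 * p["specificity"]))
  }
  invisible(x)
}
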