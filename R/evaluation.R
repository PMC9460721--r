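# Segment-based evaluation: confusion counts, percentage metrics,
# false predictions per interictal hour, and per-patient summary tables.
# Positive class = preictal throughout.

#' Confusion matrix for preictal/interictal predictions
#'
#' @param truth,pred character vectors of equal length with values
#'   `"preictal"` / `"interictal"`.
#' @return object of class `confusion` with integer fields `tp`, `fn`,
#'   `tn`, `fp` (positive = preictal).
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length")
  ok <- c("preictal", "interictal")
  if (!all(truth %in% ok) || !all(pred %in% ok))
    stop("labels must be 'preictal' or 'interictal'")
  structure(list(
    tp = sum(truth == "preictal" & pred == "preictal"),
    fn = sum(truth == "preictal" & pred == "interictal"),
    tn = sum(truth == "interictal" & pred == "interictal"),
    fp = sum(truth == "interictal" & pred == "preictal")),
    class = "confusion")
}

#' Accuracy, sensitivity and specificity from a confusion matrix
#'
#' Percentages: accuracy `100 (tp+tn)/total`, sensitivity `100 tp/(tp+fn)`
#' (true-positive rate over actual preictal), specificity
#' `100 tn/(tn+fp)`. A metric with zero denominator is reported as `NaN`,
#' never silently as 0.
#'
#' @param cm a [confusion()] object.
#' @return named list `accuracy`, `sensitivity`, `specificity` (percent).
#' @export
metrics <- function(cm) {
  total <- cm$tp + cm$fn + cm$tn + cm$fp
  if (total == 0) stop("empty confusion matrix")
  list(accuracy = 100 * (cm$tp + cm$tn) / total,
       sensitivity = if (cm$tp + cm$fn > 0) 100 * cm$tp / (cm$tp + cm$fn)
       else NaN,
       specificity = if (cm$tn + cm$fp > 0) 100 * cm$tn / (cm$tn + cm$fp)
       else NaN)
}

#' False predictions per interictal hour
#'
#' Raw false-positive segment count per hour of interictal data evaluated
#' (no alarm clustering; an optional refractory window can collapse
#' consecutive false alarms). Interictal hours =
#' `n_interictal_segments * segment_seconds / 3600` when computed from a
#' segment stream.
#'
#' @param fp_count number of false-positive segments (or alarms).
#' @param interictal_hours hours of interictal data evaluated (> 0).
#' @return alarms per hour.
#' @export
fpr_per_hour <- function(fp_count, interictal_hours) {
  if (interictal_hours <= 0) stop("interictal_hours must be positive")
  fp_count / interictal_hours
}

#' Per-patient metrics report
#'
#' @param patient patient identifier.
#' @param cm a [confusion()] for that patient's held-out predictions.
#' @param segment_seconds segment length used (for the FPR/h denominator).
#' @param model_name,transform bookkeeping columns.
#' @return one-row data.frame of class `metrics_report`.
#' @export
metrics_report <- function(patient, cm, segment_seconds,
                           model_name = "mlf_cnn", transform = "swt") {
  m <- metrics(cm)
  hours <- (cm$tn + cm$fp) * segment_seconds / 3600
  out <- data.frame(patient = patient, segment_s = segment_seconds,
                    transform = transform, model = model_name,
                    accuracy = m$accuracy, sensitivity = m$sensitivity,
                    specificity = m$specificity,
                    fpr_per_hour = if (hours > 0)
                      fpr_per_hour(cm$fp, hours) else NaN)
  class(out) <- c("metrics_report", "data.frame")
  out
}

#' Aggregate per-patient reports into a summary table
#'
#' Unweighted arithmetic mean over patients per metric (the convention of
#' per-patient results tables), plus min/max and the patient attaining
#' each. `NaN` metrics are excluded from the averages with a message.
#' Full precision is retained; rounding is for display only.
#'
#' @param reports data.frame with columns `patient`, `segment_s` and
#'   metric columns (`accuracy`, `sensitivity`, `specificity`, optionally
#'   `fpr_per_hour`).
#' @return list with `mean`, `min`, `max` (named numeric vectors) and
#'   `min_patient`, `max_patient` (named character vectors).
#' @export
aggregate_metrics <- function(reports) {
  if (NROW(reports) < 1) stop("need at least one report")
  if (length(unique(reports$segment_s)) > 1)
    stop("mixed segment lengths in one summary: ",
         paste(unique(reports$segment_s), collapse = ", "))
  cols <- intersect(c("accuracy", "sensitivity", "specificity",
                      "fpr_per_hour"), names(reports))
  mean_v <- min_v <- max_v <- setNames(numeric(length(cols)), cols)
  min_p <- max_p <- setNames(character(length(cols)), cols)
  for (cl in cols) {
    v <- reports[[cl]]
    ok <- is.finite(v)
    if (!all(ok))
      message(sum(!ok), " undefined value(s) excluded from mean ", cl)
    mean_v[cl] <- mean(v[ok])
    min_v[cl] <- min(v[ok]); max_v[cl] <- max(v[ok])
    min_p[cl] <- reports$patient[ok][which.min(v[ok])]
    max_p[cl] <- reports$patient[ok][which.max(v[ok])]
  }
  list(mean = mean_v, min = min_v, max = max_v,
       min_patient = min_p, max_patient = max_p, n = NROW(reports))
}

#' Published per-patient reference results
#'
#' Per-patient accuracy/sensitivity/specificity cells of the original
#' CHB-MIT (23 patients; VGG16 and the multi-level-feature CNN, CWT and
#' SWT images, 1 s and 3 s segments) and ZJU4H (8 patients) evaluations,
#' bundled so the table-aggregation routines can be validated against the
#' published "Average" rows by in-package arithmetic. These numbers are
#' transcribed results of GPU-scale training on external clinical data;
#' the package does not recompute them.
#'
#' @return data.frame with columns `dataset`, `model`, `transform`,
#'   `segment_s`, `patient`, `accuracy`, `sensitivity`, `specificity`.
#' @export
reference_results <- function() {
  path <- system.file("extdata", "reference_results.csv",
                      package = "ssqeeg", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}
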