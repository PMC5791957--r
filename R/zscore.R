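# Single-feature z-score baseline classifier. The comparison baseline for
# the cascade: one MP feature, per-class mean and standard deviation from
# the Training Group, z = (mp - mean_T) / sd_T. A sample is pre-classified
# into class T when |z| <= 0.25 (core per-class performance), and finally
# classified into the class with the smallest |z|.

#' Fit a single-feature z-score model
#'
#' @param values feature measurements (Training Group).
#' @param stroke_labels stroke count per measurement (>= 2 per class).
#' @param mfc_code the feature's MFC code (metadata).
#' @return object of class `gum_zscore_model`: per-class `mean` and sample
#'   (`n-1`) `sd`, plus `classes` and `mfc_code`.
#' @export
fit_zscore_model <- function(values, stroke_labels, mfc_code = NA_character_) {
  f <- factor(stroke_labels, levels = sort(unique(stroke_labels)))
  if (any(table(f) < 2L)) {
    stop_gummix("every class needs >= 2 training samples", "input")
  }
  m <- tapply(values, f, mean)
  s <- tapply(values, f, sd)
  if (any(s <= 0)) {
    stop_gummix("zero within-class variance: z-score undefined", "input")
  }
  structure(list(classes = as.integer(levels(f)), mean = as.numeric(m),
                 sd = as.numeric(s), mfc_code = mfc_code),
            class = "gum_zscore_model")
}

#' z-score of a measurement against one class
#'
#' @param mp_value feature measurement(s).
#' @param model a `gum_zscore_model`.
#' @param T class (stroke count) to score against.
#' @return `z = (mp - mean_T) / sd_T`.
#' @export
zscore <- function(mp_value, model, T) {
  i <- match(T, model$classes)
  if (is.na(i)) stop_gummix(paste0("unknown class T = ", T), "input")
  (mp_value - model$mean[i]) / model$sd[i]
}

#' Pre-classification: does the measurement belong to class T?
#'
#' @inheritParams zscore
#' @return `TRUE` iff `|z| <= 0.25` (boundary inclusive).
#' @export
zscore_preclassify <- function(mp_value, model, T) {
  abs(zscore(mp_value, model, T)) <= 0.25
}

#' Classify a measurement into the closest class by |z|
#'
#' Ties resolve to the smaller stroke count (the conservative ME).
#'
#' @param mp_value feature measurement(s).
#' @param model a `gum_zscore_model`.
#' @return integer class per measurement.
#' @export
zscore_classify <- function(mp_value, model) {
  vapply(mp_value, function(x) {
    z <- abs((x - model$mean) / model$sd)
    model$classes[which.min(z)]  # which.min takes the first (smallest t) tie
  }, integer(1))
}

#' Evaluate the z-score baseline (core per-class MCC and global score)
#'
#' Fits the model on training rows and reports, per class T, the MCC of
#' the `|z| <= 0.25` pre-classification on the test rows, plus the pooled
#' one-vs-rest MCC of the final argmin-|z| classification.
#'
#' @param train_values,train_labels training measurements and classes.
#' @param test_values,test_labels held-out measurements and classes.
#' @param mfc_code feature code (metadata).
#' @return list with `model`, `core` (data frame `T`, `mcc`), `global_mcc`.
#' @export
evaluate_zscore_baseline <- function(train_values, train_labels,
                                     test_values, test_labels,
                                     mfc_code = NA_character_) {
  model <- fit_zscore_model(train_values, train_labels, mfc_code)
  core <- do.call(rbind, lapply(model$classes, function(T) {
    pred <- zscore_preclassify(test_values, model, T)
    cc <- binary_confusion(pred, test_labels == T)
    data.frame(T = T, mcc = mcc(cc))
  }))
  P <- zscore_classify(test_values, model)
  pooled <- Reduce(function(acc, T) {
    cc <- binary_confusion(P == T, test_labels == T)
    Map(`+`, acc, cc)
  }, model$classes, init = list(tp = 0, tn = 0, fp = 0, fn = 0))
  list(model = model, core = core, global_mcc = mcc(pooled))
}
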