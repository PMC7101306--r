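# Evaluation: confusion matrix, precision/recall/accuracy with RA as the
# positive class, Cohen's kappa, the two-image ablation comparison, and
# single-field counterfactual probes of a trained model.

#' Confusion matrix for RA/nonRA labels
#'
#' @param truth,predicted equal-length vectors over `{"RA", "nonRA"}`.
#' @return A 2x2 integer matrix of class `tda_confusion`, rows = true
#'   label, columns = predicted label, RA first.
#' @export
confusion <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  ok <- c("RA", "nonRA")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'RA' or 'nonRA'")
  }
  m <- table(factor(truth, levels = ok), factor(predicted, levels = ok))
  out <- matrix(as.integer(m), 2, 2,
                dimnames = list(true = ok, predicted = ok))
  class(out) <- c("tda_confusion", class(out))
  out
}

#' Build a confusion matrix directly from its four counts
#'
#' @param tp,fn,fp,tn counts: true RA predicted RA, true RA predicted
#'   nonRA, true nonRA predicted RA, true nonRA predicted nonRA.
#' @return A `tda_confusion`.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  out <- matrix(as.integer(c(tp, fp, fn, tn)), 2, 2,
                dimnames = list(true = c("RA", "nonRA"),
                                predicted = c("RA", "nonRA")))
  if (any(out < 0)) stop("counts must be nonnegative")
  class(out) <- c("tda_confusion", class(out))
  out
}

# round half up to integer (10/11 -> 91, not banker's 90)
round_half_up <- function(x) floor(x + 0.5)

#' Precision, recall and accuracy from a confusion matrix
#'
#' RA is the positive class. Report values are rounded half-up to integer
#' percent (the convention of the source report); exact fractions are
#' retained alongside. A metric with a zero denominator is `NA` and
#' flagged undefined rather than reported as zero.
#'
#' @param cm a `tda_confusion`.
#' @return List of class `tda_metrics`: `precision`, `recall`, `accuracy`
#'   (exact fractions), `precision_pct`, `recall_pct`, `accuracy_pct`
#'   (integer percent), and `undefined` (character vector of metrics with
#'   zero denominators).
#' @export
prf_accuracy <- function(cm) {
  stopifnot(inherits(cm, "tda_confusion"))
  tp <- cm["RA", "RA"]; fn <- cm["RA", "nonRA"]
  fp <- cm["nonRA", "RA"]; tn <- cm["nonRA", "nonRA"]
  total <- tp + fn + fp + tn
  undefined <- character(0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_
  }
  accuracy <- if (total > 0) (tp + tn) / total else {
    undefined <- c(undefined, "accuracy"); NA_real_
  }
  pct <- function(x) if (is.na(x)) NA_real_ else round_half_up(100 * x)
  structure(list(precision = precision, recall = recall,
                 accuracy = accuracy, precision_pct = pct(precision),
                 recall_pct = pct(recall), accuracy_pct = pct(accuracy),
                 undefined = undefined),
            class = "tda_metrics")
}

#' @export
print.tda_metrics <- function(x, ...) {
  fmt <- function(p, e) if (is.na(p)) "undefined" else
    sprintf("%d%% (%.4f)", p, e)
  cat("precision:", fmt(x$precision_pct, x$precision), "\n")
  cat("recall:   ", fmt(x$recall_pct, x$recall), "\n")
  cat("accuracy: ", fmt(x$accuracy_pct, x$accuracy), "\n")
  invisible(x)
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), with p_o
#' the observed agreement and p_e the chance agreement from the raters'
#' marginals. When p_e = 1 (both raters constant and identical) kappa is 1.
#'
#' @param rater_a,rater_b equal-length label vectors (any label set).
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  if (length(rater_a) != length(rater_b)) {
    stop("rater vectors must have equal length")
  }
  if (length(rater_a) == 0) stop("need at least one rating")
  a <- as.character(rater_a); b <- as.character(rater_b)
  n <- length(a)
  levels <- union(unique(a), unique(b))
  p_o <- mean(a == b)
  p_e <- sum(vapply(levels, function(l) mean(a == l) * mean(b == l),
                    numeric(1)))
  if (1 - p_e < .Machine$double.eps) return(1)
  (p_o - p_e) / (1 - p_e)
}

#' Ablation comparison: full vs cruciform-only vs clinical-only images
#'
#' Encodes the same learning and test records as three image variants
#' (full image, joint blocks only, clinical squares only), runs the
#' five-trial protocol on each with the same config and seeds, and reports
#' the selected accuracy per variant.
#'
#' @param learning_records,test_records labelled record lists (disjoint
#'   patient ids).
#' @param config a [training_config()].
#' @param rules,palette,layout encoder configuration.
#' @return List of class `tda_ablation`: `report` (data.frame of variant,
#'   selected accuracy and per-trial accuracies) and `runs` (the three
#'   `tda_trials` objects).
#' @export
ablation_report <- function(learning_records, test_records,
                            config = training_config(),
                            rules = default_rules(),
                            palette = default_palette(),
                            layout = default_layout()) {
  variants <- list(full = NULL, cruciform_only = "cruciform_only",
                   clinical_only = "clinical_only")
  runs <- list()
  rows <- list()
  for (v in names(variants)) {
    learn <- encode_cohort(learning_records, config$resolution,
                           ablation = variants[[v]], rules = rules,
                           palette = palette, layout = layout)
    test <- encode_cohort(test_records, config$resolution,
                          ablation = variants[[v]], rules = rules,
                          palette = palette, layout = layout)
    runs[[v]] <- run_trials(learn, test, config)
    rows[[v]] <- data.frame(
      variant = v,
      selected_accuracy = runs[[v]]$accuracies[runs[[v]]$selected],
      accuracies = paste(sprintf("%.2f", runs[[v]]$accuracies),
                         collapse = "/"))
  }
  structure(list(report = do.call(rbind, rows), runs = runs),
            class = "tda_ablation")
}

#' @export
print.tda_ablation <- function(x, ...) {
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Single-field counterfactual probe of a trained model
#'
#' Renders a record twice — as is, and with one field replaced — predicts
#' both images, and reports whether the predicted label flipped. The input
#' record is never mutated. This is the experiment behind the observation
#' that switching ACPA from negative to positive can flip a prediction.
#'
#' @param model a `tda_model`.
#' @param record a validated [patient_record()].
#' @param field a clinical field name (e.g. `"acpa"`).
#' @param new_value replacement value (must be in the field's domain).
#' @param rules,palette,layout encoder configuration.
#' @return List: `original` and `modified` (label + score), `changed` flag.
#' @export
counterfactual_probe <- function(model, record, field, new_value,
                                 rules = default_rules(),
                                 palette = default_palette(),
                                 layout = default_layout()) {
  if (!field %in% tda_clinical_fields()) {
    stop("unknown clinical field: ", field)
  }
  modified <- record
  modified[[field]] <- new_value
  v <- validate_record(modified)
  if (length(v) > 0) {
    stop("new value is outside the field domain: ", v[1])
  }
  res <- model$resolution
  enc <- function(r) {
    img <- render_tda(r, rules, palette, layout)
    matrix(as.vector(downscale_tda(img, res, res)) / 255, 1)
  }
  p0 <- predict(model, enc(record))
  p1 <- predict(model, enc(modified))
  list(original = list(label = p0$label, score = p0$score),
       modified = list(label = p1$label, score = p1$score),
       changed = p0$label != p1$label)
}
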