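#' Decision threshold achieving a target true-positive rate
#'
#' Known samples are the positive class and are accepted when their
#' uncertainty score is at or below \eqn{\lambda}. The threshold is the
#' k-th smallest known score with `k = ceiling(level * n_known)`: the
#' smallest order statistic guaranteeing TPR >= `level`. With small known
#' sets the achieved TPR can exceed the target; it is reported alongside
#' by [evaluate_scores()].
#'
#' @param known_scores uncertainty scores of the known-class samples.
#' @param level target true-positive rate in `(0, 1]` (default 0.95).
#' @return The threshold \eqn{\lambda} (a single number).
#' @export
threshold_at_tpr <- function(known_scores, level = 0.95) {
  v <- as.numeric(known_scores)
  if (length(v) < 1L) ke_input_error("known score set is empty")
  if (!all(is.finite(v))) ke_input_error("known scores contain non-finite values")
  check_scalar_number(level, "level")
  if (level <= 0 || level > 1) ke_parameter_error("level must lie in (0, 1]")
  sort(v)[ceiling(level * length(v))]
}

#' False-positive rate at a target true-positive rate (FPR@TPR95)
#'
#' With \eqn{\lambda} chosen by [threshold_at_tpr()] so that at least
#' `level` of the known samples are accepted, the FPR is the fraction of
#' unknown samples wrongly accepted as known (score <= \eqn{\lambda}).
#' Lower is better; `level = 0.95` gives the standard FPR@TPR95.
#'
#' @inheritParams threshold_at_tpr
#' @param unknown_scores uncertainty scores of the unknown-class samples.
#' @return FPR as a fraction in `[0, 1]`.
#' @export
fpr_at_tpr <- function(known_scores, unknown_scores, level = 0.95) {
  u <- as.numeric(unknown_scores)
  if (length(u) < 1L) ke_input_error("unknown score set is empty")
  if (!all(is.finite(u))) ke_input_error("unknown scores contain non-finite values")
  lambda <- threshold_at_tpr(known_scores, level)
  mean(u <= lambda)
}

#' Area under the ROC curve (known-positive convention)
#'
#' Rank-based (Mann-Whitney) estimate of the probability that an unknown
#' sample's uncertainty score exceeds a known sample's, with half credit
#' for ties: `P(S_unknown > S_known) + 0.5 * P(S_unknown = S_known)`.
#' Equals exhaustive pair counting exactly. 1.0 is perfect separation,
#' 0.5 is chance.
#'
#' @inheritParams fpr_at_tpr
#' @return AUROC as a fraction in `[0, 1]`.
#' @export
auroc <- function(known_scores, unknown_scores) {
  k <- as.numeric(known_scores)
  u <- as.numeric(unknown_scores)
  if (length(k) < 1L) ke_input_error("known score set is empty")
  if (length(u) < 1L) ke_input_error("unknown score set is empty")
  if (!all(is.finite(c(k, u)))) ke_input_error("scores contain non-finite values")
  r <- rank(c(u, k), ties.method = "average")
  nu <- length(u)
  (sum(r[seq_len(nu)]) - nu * (nu + 1) / 2) / (nu * length(k))
}

#' Closed-set accuracy over the known-labelled samples
#'
#' Fraction of known test samples whose predicted known class matches
#' the true class. Unknown samples are excluded: this measures the
#' closed-set discrimination that open-set rejection sits on top of.
#'
#' @param predicted character vector of predicted class labels.
#' @param true_classes character vector of true class labels, same order.
#' @return Accuracy as a fraction in `[0, 1]`.
#' @export
closed_set_accuracy <- function(predicted, true_classes) {
  if (length(predicted) < 1L) ke_input_error("no known samples to evaluate")
  if (length(predicted) != length(true_classes))
    ke_alignment_error("predicted and true class vectors differ in length")
  mean(as.character(predicted) == as.character(true_classes))
}

#' Full open-set metrics report
#'
#' Computes the complete evaluation protocol for one score vector split
#' into known and unknown samples: FPR at the target TPR, AUROC,
#' closed-set accuracy (when predictions are supplied), the governing
#' threshold \eqn{\lambda} with its confusion counts, and the achieved
#' TPR. \eqn{\lambda} is derived from the known scores at `tpr_level`
#' unless `lambda_override` is set in `config`; the FPR@TPR metric is
#' always reported at the derived threshold so it stays comparable
#' across runs.
#'
#' @inheritParams fpr_at_tpr
#' @param predictions optional predicted classes for the known samples.
#' @param true_classes optional true classes for the known samples.
#' @param config a [decision_config()].
#' @return An object of class `ke_metrics`: a list with elements
#'   `fpr_at_tpr95`, `auroc`, `accuracy_known`, `lambda_used`,
#'   `tpr_level`, `tpr_achieved`, `confusion` (TP, FN, FP, TN),
#'   `n_known`, `n_unknown`.
#' @export
evaluate_scores <- function(known_scores, unknown_scores, predictions = NULL,
                            true_classes = NULL, config = decision_config()) {
  if (!inherits(config, "ke_decision_config"))
    ke_config_error("'config' must be a decision_config()")
  k <- as.numeric(known_scores)
  u <- as.numeric(unknown_scores)
  lambda_derived <- threshold_at_tpr(k, config$tpr_level)
  lambda_used <- config$lambda_override %||% lambda_derived
  fpr <- fpr_at_tpr(k, u, config$tpr_level)
  auc <- auroc(k, u)
  acc <- if (!is.null(predictions)) {
    closed_set_accuracy(predictions, true_classes)
  } else {
    NA_real_
  }
  tp <- sum(k <= lambda_used)   # known accepted as known
  fn <- sum(k > lambda_used)    # known rejected
  fp <- sum(u <= lambda_used)   # unknown accepted as known
  tn <- sum(u > lambda_used)    # unknown rejected
  structure(list(
    fpr_at_tpr95 = fpr,
    auroc = auc,
    accuracy_known = acc,
    lambda_used = lambda_used,
    tpr_level = config$tpr_level,
    tpr_achieved = mean(k <= lambda_used),
    confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
    n_known = length(k),
    n_unknown = length(u)
  ), class = "ke_metrics")
}

#' @export
print.ke_metrics <- function(x, ...) {
  cat(sprintf(
    paste0("<ke_metrics> n_known=%d n_unknown=%d\n",
           "  FPR@TPR%.0f = %.4f   AUROC = %.4f   accuracy(known) = %s\n",
           "  lambda = %.6g   achieved TPR = %.4f\n",
           "  confusion: TP=%d FN=%d FP=%d TN=%d\n"),
    x$n_known, x$n_unknown,
    100 * x$tpr_level, x$fpr_at_tpr95, x$auroc,
    if (is.na(x$accuracy_known)) "NA" else sprintf("%.4f", x$accuracy_known),
    x$lambda_used, x$tpr_achieved,
    x$confusion[["TP"]], x$confusion[["FN"]],
    x$confusion[["FP"]], x$confusion[["TN"]]))
  invisible(x)
}

# Flat list form used for JSON serialization of a report.
metrics_as_list <- function(m) {
  list(
    fpr_at_tpr95 = m$fpr_at_tpr95,
    auroc = m$auroc,
    accuracy_known = if (is.na(m$accuracy_known)) NULL else m$accuracy_known,
    lambda_used = m$lambda_used,
    tpr_level = m$tpr_level,
    tpr_achieved = m$tpr_achieved,
    TP = unname(m$confusion[["TP"]]),
    FN = unname(m$confusion[["FN"]]),
    FP = unname(m$confusion[["FP"]]),
    TN = unname(m$confusion[["TN"]]),
    n_known = m$n_known,
    n_unknown = m$n_unknown
  )
}
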