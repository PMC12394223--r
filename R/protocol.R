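#' Open-set class split
#'
#' The disjoint partition of classes into known (seen at training) and
#' unknown (appearing only at test time). Use [validate_split()] before
#' evaluation.
#'
#' @param known_classes character vector of known class labels.
#' @param unknown_classes character vector of unknown class labels.
#' @return An object of class `ke_split`.
#' @export
open_set_split <- function(known_classes, unknown_classes) {
  structure(list(known = unique(as.character(known_classes)),
                 unknown = unique(as.character(unknown_classes))),
            class = "ke_split")
}

#' Validate an open-set split
#'
#' Checks the open-set conditions: the known and unknown class sets must
#' be disjoint and both non-empty for evaluation. Returns the split
#' unchanged when valid.
#'
#' @param split an [open_set_split()].
#' @return The validated split.
#' @export
validate_split <- function(split) {
  if (!inherits(split, "ke_split"))
    ke_protocol_error("'split' must be an open_set_split()")
  if (length(split$known) == 0L)
    ke_protocol_error("open-set split has no known classes")
  if (length(split$unknown) == 0L)
    ke_protocol_error("open-set split has no unknown classes")
  overlap <- intersect(split$known, split$unknown)
  if (length(overlap) > 0L)
    ke_protocol_error(sprintf(
      "known and unknown classes must be disjoint; overlapping: %s",
      paste(overlap, collapse = ", ")))
  split
}

#' Per-sample ground truth for open-set evaluation
#'
#' Records each test sample's membership (known or unknown class) and its
#' actual class label (retained for unknown samples too, for reporting).
#'
#' @param sample_ids unique sample identifiers.
#' @param membership `"known"` or `"unknown"` per sample.
#' @param class_label the sample's class, per sample.
#' @return An object of class `ke_truth`.
#' @export
ground_truth <- function(sample_ids, membership, class_label) {
  sample_ids <- as.character(sample_ids)
  membership <- as.character(membership)
  class_label <- as.character(class_label)
  if (anyDuplicated(sample_ids)) ke_input_error("sample ids must be unique")
  n <- length(sample_ids)
  if (length(membership) != n || length(class_label) != n)
    ke_alignment_error("membership and class_label must match sample_ids in length")
  bad <- setdiff(unique(membership), c("known", "unknown"))
  if (length(bad) > 0L)
    ke_input_error(sprintf("membership values must be 'known' or 'unknown' (got %s)",
                           paste(bad, collapse = ", ")))
  structure(list(sample_ids = sample_ids, membership = membership,
                 class_label = class_label),
            class = "ke_truth")
}

# Split implied by the ground truth (known = classes of known samples).
split_from_truth <- function(truth) {
  open_set_split(sort(unique(truth$class_label[truth$membership == "known"])),
                 sort(unique(truth$class_label[truth$membership == "unknown"])))
}

#' Few-shot protocol configuration
#'
#' @param shots samples per known class, `M`: a positive integer
#'   (benchmark presets use 2, 4, 8 or 16) or `"all"` to keep the whole
#'   bank.
#' @param seed integer seed for the subsampling draw.
#' @return An object of class `ke_shot_config`.
#' @export
shot_config <- function(shots = "all", seed = 1L) {
  if (!identical(shots, "all")) {
    check_scalar_number(shots, "shots")
    if (shots < 1 || shots != round(shots))
      ke_parameter_error("shots must be a positive integer or 'all'")
    shots <- as.integer(shots)
  }
  check_scalar_number(seed, "seed")
  structure(list(shots = shots, seed = as.integer(seed)),
            class = "ke_shot_config")
}

#' M-shot subsampling of a training feature bank
#'
#' Draws exactly `M` rows per known class, uniformly without replacement
#' under the configured seed. Implemented as a seeded per-class shuffle
#' with prefix selection, so shot counts are nested: the 2-shot subset is
#' contained in the 4-shot subset, and so on, enabling monotone few-shot
#' ablations. Deterministic given `(bank, shots, seed)`.
#'
#' @param bank a [feature_bank()].
#' @param config a [shot_config()]; with `shots = "all"` the bank is
#'   returned unchanged.
#' @return A [feature_bank()] with `M` rows per class (classes in sorted
#'   order).
#' @export
few_shot_subsample <- function(bank, config = shot_config()) {
  if (!inherits(bank, "ke_bank"))
    ke_input_error("'bank' must be a feature_bank()")
  if (!inherits(config, "ke_shot_config"))
    ke_config_error("'config' must be a shot_config()")
  if (identical(config$shots, "all")) return(bank)
  m <- config$shots
  classes <- sort(unique(bank$classes))
  keep <- withr::with_seed(config$seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(bank$classes == cl)
      if (length(idx) < m)
        ke_data_error(sprintf(
          "class '%s' has only %d bank rows, fewer than shots = %d",
          cl, length(idx), m))
      sample(idx)[seq_len(m)]
    }), use.names = FALSE)
  })
  emb <- bank$embeddings
  feature_bank(
    embedding_matrix(emb$values[keep, , drop = FALSE],
                     space_tag = emb$space_tag,
                     sample_ids = emb$sample_ids[keep],
                     l2_normalized = emb$l2_normalized),
    bank$classes[keep])
}

# Internal: closed-set predictions from logits or image-text similarity.
predict_known_class <- function(test_logits = NULL, test_feats_ft = NULL,
                                text_feats = NULL) {
  if (!is.null(test_logits)) {
    cls <- test_logits$class_names[max.col(test_logits$values,
                                           ties.method = "first")]
    return(setNames(cls, test_logits$sample_ids))
  }
  if (!is.null(test_feats_ft) && !is.null(text_feats)) {
    sims <- cosine_similarity(test_feats_ft$values, text_feats$values,
                              "image features", "text features")
    cls <- text_feats$class_names[max.col(sims, ties.method = "first")]
    return(setNames(cls, test_feats_ft$sample_ids))
  }
  NULL
}

#' Run the knowledge-ensemble scoring pipeline end to end
#'
#' Computes the requested ensemble components — category prediction
#' distribution (CPD, from logits or image-text concept matching),
#' domain-specific knowledge (DSK, fine-tuned feature space) and general
#' knowledge (GK, frozen pretrained feature space) — min-max normalizes
#' each over the test set, fuses them by the chosen mode, and evaluates
#' open-set metrics for the final score and for every single component
#' (ablation style). Training banks are checked against the split: a bank
#' containing unknown-class rows is a protocol violation.
#'
#' @param test_feats_ft test [embedding_matrix()] in the fine-tuned space.
#' @param test_feats_pt test [embedding_matrix()] in the pretrained space.
#' @param bank_ft,bank_pt training [feature_bank()]s in the matching
#'   spaces, built from known classes only.
#' @param truth a [ground_truth()] covering all test samples.
#' @param test_logits optional [logit_matrix()] (required for logit-based
#'   CPD methods and used for closed-set predictions).
#' @param text_feats optional [text_embeddings()] (required for the
#'   `mcm` CPD base; also used for predictions when logits are absent).
#' @param spec an [ensemble_spec()].
#' @param decision a [decision_config()].
#' @param temperature temperature passed to the CPD base score.
#' @param split optional [open_set_split()]; derived from `truth` when
#'   omitted.
#' @return An object of class `ke_result`: list with `scores` (named
#'   list of per-component and final [score_vector()]s), `metrics` (the
#'   final-score `ke_metrics`), `component_metrics` (named list of
#'   `ke_metrics`), `decisions` (per-sample known/unknown at the
#'   governing threshold), `lambda`, `split` and `spec`.
#' @export
run_knowledge_ensemble <- function(test_feats_ft, test_feats_pt, bank_ft,
                                   bank_pt, truth, test_logits = NULL,
                                   text_feats = NULL,
                                   spec = ensemble_spec("visual_three_way"),
                                   decision = decision_config(),
                                   temperature = 1, split = NULL) {
  if (!inherits(truth, "ke_truth"))
    ke_input_error("'truth' must be a ground_truth()")
  split <- validate_split(split %||% split_from_truth(truth))
  for (nm in c("bank_ft", "bank_pt")) {
    bank <- get(nm)
    if (!inherits(bank, "ke_bank"))
      ke_input_error(sprintf("'%s' must be a feature_bank()", nm))
    illegal <- setdiff(unique(bank$classes), split$known)
    if (length(illegal) > 0L)
      ke_protocol_error(sprintf(
        "%s contains rows from non-known class(es): %s",
        nm, paste(illegal, collapse = ", ")))
  }
  ids <- truth$sample_ids
  if (!identical(test_feats_ft$sample_ids, ids) ||
      !identical(test_feats_pt$sample_ids, ids))
    ke_alignment_error("test embeddings and ground truth disagree on sample ids")
  if (!is.null(test_logits) && !identical(test_logits$sample_ids, ids))
    ke_alignment_error("test logits and ground truth disagree on sample ids")

  comps <- list()
  if ("cpd" %in% spec$components) {
    comps$cpd <- cpd_score(logits = test_logits, method = spec$base_cpd_method,
                           temperature = temperature,
                           image_feats = test_feats_ft, text_feats = text_feats)
  }
  if ("dsk" %in% spec$components)
    comps$dsk <- dsk_score(test_feats_ft, bank_ft)
  if ("gk" %in% spec$components)
    comps$gk <- gk_score(test_feats_pt, bank_pt)

  final <- ensemble_score(unname(comps), spec)

  known_mask <- truth$membership == "known"
  preds <- predict_known_class(test_logits, test_feats_ft, text_feats)
  eval_one <- function(s) {
    evaluate_scores(
      known_scores = as.numeric(s)[known_mask],
      unknown_scores = as.numeric(s)[!known_mask],
      predictions = if (!is.null(preds)) preds[known_mask] else NULL,
      true_classes = if (!is.null(preds)) truth$class_label[known_mask] else NULL,
      config = decision)
  }
  final_metrics <- eval_one(final)
  component_metrics <- lapply(comps, eval_one)

  structure(list(
    scores = c(comps, list(ensemble = final)),
    metrics = final_metrics,
    component_metrics = component_metrics,
    decisions = decide(final, final_metrics$lambda_used),
    lambda = final_metrics$lambda_used,
    split = split,
    spec = spec
  ), class = "ke_result")
}

#' @export
print.ke_result <- function(x, ...) {
  cat(sprintf("<ke_result> mode=%s components={%s}\n", x$spec$mode,
              paste(x$spec$components, collapse = ", ")))
  cat("final: ")
  print(x$metrics)
  for (nm in names(x$component_metrics)) {
    m <- x$component_metrics[[nm]]
    cat(sprintf("  %-4s AUROC = %.4f  FPR@TPR%.0f = %.4f\n",
                nm, m$auroc, 100 * m$tpr_level, m$fpr_at_tpr95))
  }
  invisible(x)
}

#' Export score distributions as a numeric histogram table
#'
#' Bins the uncertainty scores of the known and unknown groups over a
#' common grid — `[0, 1]` for normalized scores, the observed score range
#' otherwise — so the separation between the two distributions can be
#' inspected or plotted without any figure machinery. Counts sum to the
#' group sizes.
#'
#' @param scores a [score_vector()] over all test samples.
#' @param truth a [ground_truth()] with matching sample ids.
#' @param bins number of equal-width bins (>= 2).
#' @return A data.frame with columns `bin`, `lower`, `upper`, `known`,
#'   `unknown`.
#' @export
export_score_distributions <- function(scores, truth, bins = 20L) {
  check_scalar_number(bins, "bins")
  if (bins < 2 || bins != round(bins))
    ke_parameter_error("bins must be an integer >= 2")
  bins <- as.integer(bins)
  if (!inherits(truth, "ke_truth"))
    ke_input_error("'truth' must be a ground_truth()")
  if (!identical(names(scores), truth$sample_ids))
    ke_alignment_error("scores and ground truth disagree on sample ids")
  v <- as.numeric(scores)
  if (inherits(scores, "ke_scores") && score_normalized(scores)) {
    lo <- 0; hi <- 1
  } else {
    lo <- min(v); hi <- max(v)
    if (hi == lo) hi <- lo + 1e-12
  }
  breaks <- seq(lo, hi, length.out = bins + 1L)
  count_group <- function(mask) {
    if (!any(mask)) return(integer(bins))
    # left-closed bins, highest bin closed on both ends
    tabulate(findInterval(v[mask], breaks, rightmost.closed = TRUE,
                          all.inside = TRUE), nbins = bins)
  }
  data.frame(
    bin = seq_len(bins),
    lower = breaks[-(bins + 1L)],
    upper = breaks[-1L],
    known = count_group(truth$membership == "known"),
    unknown = count_group(truth$membership == "unknown")
  )
}
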