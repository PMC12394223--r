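#' Per-sample classifier logits over the known classes
#'
#' Container for an `n x K` matrix of pre-softmax class scores from a
#' classification head, one row per test sample. The logits feed the
#' category-prediction-distribution family of uncertainty scores
#' ([max_logit_score()], [energy_score()], [cpd_score()]).
#'
#' @param values numeric `n x K` matrix; row `i` holds the logits `z` of
#'   sample `i` over the `K` known classes. All entries must be finite.
#' @param sample_ids character vector of `n` unique sample identifiers.
#'   Defaults to `rownames(values)`, then `"s1".."sn"`.
#' @param class_names character vector of `K` unique class labels.
#'   Defaults to `colnames(values)`, then `"class1".."classK"`.
#' @return An object of class `ke_logits` with elements `values`,
#'   `sample_ids`, `class_names`.
#' @examples
#' logit_matrix(rbind(c(3, 1, 0.5)), class_names = c("a", "b", "c"))
#' @export
logit_matrix <- function(values, sample_ids = NULL, class_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) ke_input_error("logit matrix must have at least one row")
  if (ncol(values) < 1L) ke_input_error("logit matrix must have at least one class")
  if (!all(is.finite(values))) ke_input_error("logit matrix contains non-finite values")
  sample_ids <- as.character(sample_ids %||% rownames(values) %||%
                               paste0("s", seq_len(nrow(values))))
  class_names <- as.character(class_names %||% colnames(values) %||%
                                paste0("class", seq_len(ncol(values))))
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids))
    ke_input_error("sample_ids must be unique and match the number of rows")
  if (length(class_names) != ncol(values) || anyDuplicated(class_names))
    ke_input_error("class_names must be unique and match the number of columns")
  dimnames(values) <- list(sample_ids, class_names)
  structure(list(values = values, sample_ids = sample_ids,
                 class_names = class_names),
            class = "ke_logits")
}

#' Image-encoder embeddings in a tagged model space
#'
#' Container for an `n x d` matrix of image-encoder features, tagged with
#' the model space they come from: `"finetuned"` (the task-adapted
#' encoder, carrying domain-specific knowledge) or `"pretrained"` (the
#' frozen original encoder, carrying general knowledge). The tag prevents
#' accidentally comparing features across incompatible spaces.
#'
#' @param values numeric `n x d` matrix of embeddings; finite, no
#'   all-zero rows (cosine similarity is undefined at zero).
#' @param space_tag `"finetuned"` or `"pretrained"`.
#' @param sample_ids character vector of `n` unique identifiers.
#' @param l2_normalized logical flag recording whether rows are already
#'   unit length. Scores re-normalize internally either way.
#' @return An object of class `ke_embed`.
#' @export
embedding_matrix <- function(values, space_tag = c("finetuned", "pretrained"),
                             sample_ids = NULL, l2_normalized = FALSE) {
  space_tag <- match.arg(space_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) ke_input_error("embedding matrix must have at least one row")
  if (ncol(values) < 1L) ke_input_error("embedding dimension d must be >= 1")
  if (!all(is.finite(values))) ke_input_error("embedding matrix contains non-finite values")
  sample_ids <- as.character(sample_ids %||% rownames(values) %||%
                               paste0("s", seq_len(nrow(values))))
  if (length(sample_ids) != nrow(values) || anyDuplicated(sample_ids))
    ke_input_error("sample_ids must be unique and match the number of rows")
  rownames(values) <- sample_ids
  zero <- which(rowSums(values^2) == 0)
  if (length(zero) > 0L)
    ke_input_error(sprintf("all-zero embedding row(s): %s",
                           paste(head(sample_ids[zero], 5L), collapse = ", ")))
  structure(list(values = values, sample_ids = sample_ids,
                 space_tag = space_tag, l2_normalized = isTRUE(l2_normalized)),
            class = "ke_embed")
}

#' Training-set feature bank
#'
#' Stored embeddings of the training samples, with the known-class label
#' of every row. Test embeddings are matched against the bank by maximum
#' cosine similarity ([knn_dissimilarity()]); the bank's `space_tag` must
#' match the query's.
#'
#' @param embeddings an [embedding_matrix()] of training samples.
#' @param classes character vector: known-class label of each bank row.
#' @return An object of class `ke_bank`.
#' @export
feature_bank <- function(embeddings, classes) {
  if (!inherits(embeddings, "ke_embed"))
    ke_input_error("'embeddings' must be an embedding_matrix()")
  classes <- as.character(classes)
  if (length(classes) != nrow(embeddings$values))
    ke_input_error("'classes' must label every bank row")
  structure(list(embeddings = embeddings, classes = classes),
            class = "ke_bank")
}

#' Per-class text embeddings for the vision-language path
#'
#' One text-encoder embedding per known class, used by the maximum
#' concept matching score ([mcm_score()]) and for closed-set prediction
#' by image-text similarity in VLM mode.
#'
#' @param values numeric `K x d` matrix, one row per known class; finite
#'   and non-zero rows.
#' @param class_names character vector of `K` unique class labels.
#' @return An object of class `ke_text`.
#' @export
text_embeddings <- function(values, class_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) ke_input_error("text embeddings need at least one class")
  if (!all(is.finite(values))) ke_input_error("text embeddings contain non-finite values")
  class_names <- as.character(class_names %||% rownames(values) %||%
                                paste0("class", seq_len(nrow(values))))
  if (length(class_names) != nrow(values) || anyDuplicated(class_names))
    ke_input_error("class_names must be unique, one per text row")
  rownames(values) <- class_names
  zero <- which(rowSums(values^2) == 0)
  if (length(zero) > 0L)
    ke_input_error(sprintf("all-zero text embedding row(s): %s",
                           paste(class_names[zero], collapse = ", ")))
  structure(list(values = values, class_names = class_names),
            class = "ke_text")
}

#' Per-sample uncertainty score vector
#'
#' A named numeric vector of uncertainty scores with provenance
#' attributes. The direction convention is fixed package-wide: higher
#' value means more anomalous (more likely an unknown class), for every
#' score kind.
#'
#' @param values numeric vector of scores, one per sample.
#' @param sample_ids character identifiers, same order as `values`.
#' @param kind one of `"max_logit"`, `"energy"`, `"mcm"`, `"cpd"`,
#'   `"dsk"`, `"gk"`, `"ensemble"`.
#' @param normalized logical; `TRUE` when values were min-max scaled to
#'   `[0, 1]`.
#' @param temperature the temperature used to compute the score, or `NA`
#'   when not applicable.
#' @return A classed numeric vector (`ke_scores`) named by sample id.
#' @export
score_vector <- function(values, sample_ids = names(values), kind,
                         normalized = FALSE, temperature = NA_real_) {
  kinds <- c("max_logit", "energy", "mcm", "cpd", "dsk", "gk", "ensemble")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds)
    ke_parameter_error(sprintf("score kind must be one of: %s",
                               paste(kinds, collapse = ", ")))
  values <- as.numeric(values)
  if (length(values) < 1L) ke_input_error("score vector must have at least one value")
  if (!all(is.finite(values))) ke_input_error("score vector contains non-finite values")
  sample_ids <- as.character(sample_ids %||% paste0("s", seq_along(values)))
  if (length(sample_ids) != length(values) || anyDuplicated(sample_ids))
    ke_input_error("sample_ids must be unique and match the number of scores")
  if (isTRUE(normalized) && (min(values) < -1e-12 || max(values) > 1 + 1e-12))
    ke_input_error("normalized scores must lie in [0, 1]")
  structure(setNames(values, sample_ids), class = "ke_scores",
            kind = kind, normalized = isTRUE(normalized),
            temperature = as.numeric(temperature))
}

score_kind <- function(x) attr(x, "kind", exact = TRUE)
score_normalized <- function(x) isTRUE(attr(x, "normalized", exact = TRUE))

#' @export
print.ke_scores <- function(x, ...) {
  cat(sprintf("<ke_scores> kind=%s normalized=%s n=%d\n",
              score_kind(x), score_normalized(x), length(x)))
  print(unclass(structure(as.numeric(x), names = names(x))), ...)
  invisible(x)
}

#' Ensemble fusion specification
#'
#' Which score components are fused and how. The three named modes match
#' the method's variants: `visual_three_way` averages the category
#' prediction, domain-specific and general-knowledge scores
#' (CNN/ViT setting); `vlm_two_way` averages only the two feature
#' similarity scores (the recommended VLM setting); `vlm_three_way`
#' additionally mixes in maximum concept matching as the CPD base (the
#' ablated MCM+GK+DSK variant).
#'
#' @param mode `"visual_three_way"`, `"vlm_two_way"`, `"vlm_three_way"`
#'   or `"custom"`.
#' @param components for `mode = "custom"`, the score kinds to average.
#' @param base_cpd_method which base score feeds the CPD component:
#'   `"msp"`, `"raw_maxlogit"`, `"energy"` or `"mcm"`. Defaults to
#'   `"msp"` for the visual mode and `"mcm"` for `vlm_three_way`.
#' @return An object of class `ke_ensemble_spec`.
#' @export
ensemble_spec <- function(mode = c("visual_three_way", "vlm_two_way",
                                   "vlm_three_way", "custom"),
                          components = NULL, base_cpd_method = NULL) {
  mode <- match.arg(mode)
  components <- switch(mode,
    visual_three_way = c("cpd", "dsk", "gk"),
    vlm_two_way      = c("dsk", "gk"),
    vlm_three_way    = c("cpd", "dsk", "gk"),
    custom           = as.character(components))
  if (length(components) == 0L || anyDuplicated(components))
    ke_config_error("ensemble components must be a non-empty set of distinct kinds")
  base_cpd_method <- base_cpd_method %||%
    if (mode == "vlm_three_way") "mcm" else "msp"
  if (!base_cpd_method %in% c("msp", "raw_maxlogit", "energy", "mcm"))
    ke_config_error("base_cpd_method must be one of msp, raw_maxlogit, energy, mcm")
  structure(list(mode = mode, components = components,
                 base_cpd_method = base_cpd_method),
            class = "ke_ensemble_spec")
}

#' Decision-rule configuration
#'
#' Governs the rejection threshold \eqn{\lambda}: either derived from the
#' known-score distribution at a target true-positive rate (default 95%),
#' or fixed explicitly via `lambda_override`.
#'
#' @param tpr_level target true-positive rate in `(0, 1]` used to derive
#'   \eqn{\lambda} from the known scores.
#' @param lambda_override optional fixed threshold; when supplied it
#'   governs the per-sample decisions and confusion counts.
#' @return An object of class `ke_decision_config`.
#' @export
decision_config <- function(tpr_level = 0.95, lambda_override = NULL) {
  check_scalar_number(tpr_level, "tpr_level")
  if (tpr_level <= 0 || tpr_level > 1)
    ke_parameter_error("tpr_level must lie in (0, 1]")
  if (!is.null(lambda_override))
    check_scalar_number(lambda_override, "lambda_override")
  structure(list(tpr_level = tpr_level, lambda_override = lambda_override),
            class = "ke_decision_config")
}
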