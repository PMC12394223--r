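#' Max-logit family uncertainty score
#'
#' Scores each sample by the (negated) confidence of its strongest class.
#' Three dialects are provided:
#' \describe{
#'   \item{`msp`}{(default) negative maximum softmax probability of the
#'     temperature-scaled logits, \eqn{-\max_i \mathrm{softmax}(z/T)_i}.
#'     Safe for arbitrary logits and the package default.}
#'   \item{`raw_maxlogit`}{negative raw maximum logit, \eqn{-\max_i z_i}.}
#'   \item{`literal`}{negative maximum of the linearly normalized scaled
#'     logits, \eqn{-\max_i (z_i/T) / \sum_j (z_j/T)}; undefined (and
#'     rejected) when a row of scaled logits sums to zero.}
#' }
#' Higher scores mean more anomalous.
#'
#' @param logits a [logit_matrix()].
#' @param temperature positive temperature scaling factor `T`.
#' @param dialect `"msp"`, `"raw_maxlogit"` or `"literal"`.
#' @return A [score_vector()] of kind `"max_logit"`.
#' @examples
#' ml <- logit_matrix(rbind(c(3, 1, 0.5)))
#' max_logit_score(ml)  # ~ -0.821
#' @seealso [energy_score()], [cpd_score()]
#' @export
max_logit_score <- function(logits, temperature = 1,
                            dialect = c("msp", "raw_maxlogit", "literal")) {
  dialect <- match.arg(dialect)
  if (!inherits(logits, "ke_logits"))
    ke_input_error("'logits' must be a logit_matrix()")
  check_scalar_number(temperature, "temperature", positive = TRUE)
  z <- logits$values
  if (dialect != "raw_maxlogit" && ncol(z) < 2L)
    ke_input_error("softmax-type max-logit scores require K >= 2 classes")
  s <- switch(dialect,
    msp = {
      zt <- z / temperature
      m <- row_max(zt)
      # max softmax = 1 / sum(exp(z - max z)), numerically stable
      -1 / rowSums(exp(zt - m))
    },
    raw_maxlogit = -row_max(z),
    literal = {
      zt <- z / temperature
      rs <- rowSums(zt)
      zero <- which(rs == 0)
      if (length(zero) > 0L)
        ke_degenerate_error(sprintf(
          "literal max-logit dialect undefined: zero row sum for sample(s) %s",
          paste(head(logits$sample_ids[zero], 5L), collapse = ", ")))
      -row_max(zt / rs)
    })
  score_vector(s, logits$sample_ids, kind = "max_logit",
               normalized = FALSE, temperature = temperature)
}

#' Energy uncertainty score
#'
#' The negative log-sum-exp of the temperature-scaled logits,
#' \eqn{-\log \sum_i e^{z_i/T}}, computed overflow-safely. Less
#' susceptible to softmax overconfidence than the max-logit score. With a
#' single class the score reduces exactly to the negated scaled logit.
#' Higher scores mean more anomalous.
#'
#' @inheritParams max_logit_score
#' @return A [score_vector()] of kind `"energy"`.
#' @examples
#' energy_score(logit_matrix(rbind(c(0, 0))))  # -log(2)
#' @export
energy_score <- function(logits, temperature = 1) {
  if (!inherits(logits, "ke_logits"))
    ke_input_error("'logits' must be a logit_matrix()")
  check_scalar_number(temperature, "temperature", positive = TRUE)
  zt <- logits$values / temperature
  m <- row_max(zt)
  s <- -(m + log(rowSums(exp(zt - m))))
  score_vector(s, logits$sample_ids, kind = "energy",
               normalized = FALSE, temperature = temperature)
}

#' Maximum concept matching (MCM) uncertainty score
#'
#' Vision-language analogue of the maximum softmax probability: the image
#' embedding is compared to every known class's text embedding by cosine
#' similarity, and the score is the negated maximum softmax of the
#' temperature-scaled similarities,
#' \eqn{-\max_i \mathrm{softmax}(\mathrm{sim}(f, g_i)/T)}.
#' Known-class images should lie close to their class's text concept and
#' thus receive low scores. Both inputs are L2-normalized internally.
#'
#' @param image_feats an [embedding_matrix()] of test-image features.
#' @param text_feats a [text_embeddings()] object, one row per known class.
#' @param temperature positive temperature `T`.
#' @return A [score_vector()] of kind `"mcm"`.
#' @export
mcm_score <- function(image_feats, text_feats, temperature = 1) {
  if (!inherits(image_feats, "ke_embed"))
    ke_input_error("'image_feats' must be an embedding_matrix()")
  if (!inherits(text_feats, "ke_text"))
    ke_input_error("'text_feats' must be a text_embeddings()")
  check_scalar_number(temperature, "temperature", positive = TRUE)
  sims <- cosine_similarity(image_feats$values, text_feats$values,
                            "image features", "text features")
  st <- sims / temperature
  m <- row_max(st)
  s <- -1 / rowSums(exp(st - m))
  score_vector(s, image_feats$sample_ids, kind = "mcm",
               normalized = FALSE, temperature = temperature)
}

#' Nearest-neighbour cosine dissimilarity against a feature bank
#'
#' The shared kernel of the domain-specific and general-knowledge scores:
#' for each query embedding, the negated maximum cosine similarity over
#' all training-bank rows. Values lie in `[-1, 1]`; an exact duplicate of
#' a bank row scores `-1`, a query orthogonal to the whole bank scores
#' `0`. The query and bank must carry the same `space_tag` — mixing the
#' fine-tuned and pretrained spaces is a protocol error.
#'
#' @param query an [embedding_matrix()] of test samples.
#' @param bank a [feature_bank()] in the same model space.
#' @return A raw (unnormalized) [score_vector()] whose kind is `"dsk"`
#'   in the fine-tuned space and `"gk"` in the pretrained space.
#' @export
knn_dissimilarity <- function(query, bank) {
  if (!inherits(query, "ke_embed"))
    ke_input_error("'query' must be an embedding_matrix()")
  if (!inherits(bank, "ke_bank"))
    ke_input_error("'bank' must be a feature_bank()")
  if (!identical(query$space_tag, bank$embeddings$space_tag))
    ke_protocol_error(sprintf(
      "space tag mismatch: query is '%s' but bank is '%s'",
      query$space_tag, bank$embeddings$space_tag))
  if (nrow(bank$embeddings$values) < 1L)
    ke_input_error("feature bank is empty")
  sims <- cosine_similarity(query$values, bank$embeddings$values,
                            "query embeddings", "bank embeddings")
  kind <- if (query$space_tag == "finetuned") "dsk" else "gk"
  score_vector(-row_max(sims), query$sample_ids, kind = kind,
               normalized = FALSE)
}

#' Min-max normalization of a score vector
#'
#' Rescales scores to `[0, 1]` by `(s - min) / (max - min)`. By default
#' the statistics are taken over the score set itself (transductive, over
#' the full evaluated test set); a frozen pair of statistics fitted on a
#' calibration set can be supplied for single-sample deployment, in which
#' case values are clamped into `[0, 1]`. When all scores are equal the
#' whole vector maps to 0.5, so a degenerate component contributes
#' nothing to the ensemble ranking instead of producing NaNs. The
#' transform is strictly increasing, so sample rankings (and therefore
#' AUROC) are unchanged.
#'
#' @param scores a [score_vector()] (or plain numeric vector).
#' @param stats optional `c(min, max)` frozen statistics.
#' @return A [score_vector()] flagged `normalized = TRUE`, same kind.
#' @export
minmax_normalize <- function(scores, stats = NULL) {
  kind <- if (inherits(scores, "ke_scores")) score_kind(scores) else "ensemble"
  temp <- attr(scores, "temperature", exact = TRUE) %||% NA_real_
  ids <- names(scores) %||% paste0("s", seq_along(scores))
  v <- as.numeric(scores)
  if (length(v) < 1L) ke_input_error("cannot normalize an empty score vector")
  if (!all(is.finite(v))) ke_input_error("scores contain non-finite values")
  if (is.null(stats)) {
    lo <- min(v); hi <- max(v)
  } else {
    if (!is.numeric(stats) || length(stats) != 2L || !all(is.finite(stats)))
      ke_parameter_error("'stats' must be a finite numeric pair c(min, max)")
    lo <- stats[1L]; hi <- stats[2L]
    if (hi < lo) ke_parameter_error("'stats' must satisfy min <= max")
  }
  out <- if (hi == lo) rep(0.5, length(v)) else (v - lo) / (hi - lo)
  out <- pmin(1, pmax(0, out))
  score_vector(out, ids, kind = kind, normalized = TRUE, temperature = temp)
}

#' Category-prediction-distribution (CPD) ensemble component
#'
#' The normalized uncertainty score derived from the classifier's
#' category prediction distribution: a base score (`msp`,
#' `raw_maxlogit`, `energy`, or `mcm` for vision-language models) is
#' computed and min-max normalized over the evaluated sample set.
#'
#' @param logits a [logit_matrix()] (required for the logit-based
#'   methods).
#' @param method base score: `"msp"`, `"raw_maxlogit"`, `"energy"` or
#'   `"mcm"`.
#' @param temperature positive temperature for the base score.
#' @param image_feats,text_feats required when `method = "mcm"`.
#' @param base optionally, a precomputed base [score_vector()]; when
#'   supplied it is normalized directly and the other inputs are ignored.
#' @return A normalized [score_vector()] of kind `"cpd"`.
#' @export
cpd_score <- function(logits = NULL,
                      method = c("msp", "raw_maxlogit", "energy", "mcm"),
                      temperature = 1, image_feats = NULL, text_feats = NULL,
                      base = NULL) {
  method <- match.arg(method)
  if (is.null(base)) {
    base <- switch(method,
      msp = ,
      raw_maxlogit = {
        if (is.null(logits))
          ke_config_error(sprintf("cpd method '%s' requires logits", method))
        max_logit_score(logits, temperature = temperature, dialect = method)
      },
      energy = {
        if (is.null(logits))
          ke_config_error("cpd method 'energy' requires logits")
        energy_score(logits, temperature = temperature)
      },
      mcm = {
        if (is.null(image_feats) || is.null(text_feats))
          ke_config_error(
            "cpd method 'mcm' requires image_feats and text_feats")
        mcm_score(image_feats, text_feats, temperature = temperature)
      })
  } else if (!inherits(base, "ke_scores")) {
    ke_input_error("'base' must be a score_vector()")
  }
  out <- minmax_normalize(base)
  score_vector(as.numeric(out), names(out), kind = "cpd", normalized = TRUE,
               temperature = attr(base, "temperature", exact = TRUE) %||% NA_real_)
}

#' Domain-specific-knowledge (DSK) ensemble component
#'
#' Normalized nearest-neighbour cosine dissimilarity of test embeddings
#' against the training feature bank, both in the fine-tuned model space.
#' Fine-tuned encoders concentrate on task-relevant structure, so known
#' test samples land close to the bank and score low.
#'
#' @param test_feats an [embedding_matrix()] with
#'   `space_tag = "finetuned"`.
#' @param bank a [feature_bank()] in the same space.
#' @return A normalized [score_vector()] of kind `"dsk"`.
#' @export
dsk_score <- function(test_feats, bank) {
  if (!inherits(test_feats, "ke_embed") ||
      !identical(test_feats$space_tag, "finetuned"))
    ke_protocol_error("dsk_score requires embeddings tagged 'finetuned'")
  minmax_normalize(knn_dissimilarity(test_feats, bank))
}

#' General-knowledge (GK) ensemble component
#'
#' The counterpart of [dsk_score()] in the frozen pretrained model
#' space: the general knowledge of the original encoder is retained there
#' and complements what fine-tuning may have overwritten.
#'
#' @param test_feats an [embedding_matrix()] with
#'   `space_tag = "pretrained"`.
#' @param bank a [feature_bank()] in the same space.
#' @return A normalized [score_vector()] of kind `"gk"`.
#' @export
gk_score <- function(test_feats, bank) {
  if (!inherits(test_feats, "ke_embed") ||
      !identical(test_feats$space_tag, "pretrained"))
    ke_protocol_error("gk_score requires embeddings tagged 'pretrained'")
  minmax_normalize(knn_dissimilarity(test_feats, bank))
}

#' Fuse normalized score components into the ensemble score
#'
#' Element-wise arithmetic mean of the normalized components:
#' `(cpd + dsk + gk) / 3` for the visual three-way mode and
#' `(dsk + gk) / 2` for the VLM two-way mode. All components must be
#' normalized, carry identical sample ids in identical order (alignment
#' is by id; a mismatch is an error, never a silent reorder), and their
#' kinds must match the fusion specification. The fusion is
#' non-parametric: no weights are learned.
#'
#' @param components list of normalized [score_vector()]s.
#' @param spec an [ensemble_spec()].
#' @return A normalized [score_vector()] of kind `"ensemble"`.
#' @export
ensemble_score <- function(components, spec = ensemble_spec()) {
  if (!inherits(spec, "ke_ensemble_spec"))
    ke_config_error("'spec' must be an ensemble_spec()")
  if (!is.list(components) || length(components) == 0L)
    ke_input_error("'components' must be a non-empty list of score vectors")
  for (comp in components) {
    if (!inherits(comp, "ke_scores"))
      ke_input_error("every ensemble component must be a score_vector()")
    if (!score_normalized(comp))
      ke_protocol_error(sprintf(
        "ensemble component '%s' is not normalized", score_kind(comp)))
  }
  kinds <- vapply(components, score_kind, character(1))
  if (!setequal(kinds, spec$components) || anyDuplicated(kinds))
    ke_protocol_error(sprintf(
      "component kinds {%s} do not match ensemble mode '%s' (expects {%s})",
      paste(kinds, collapse = ", "), spec$mode,
      paste(spec$components, collapse = ", ")))
  ids <- names(components[[1L]])
  for (comp in components[-1L]) {
    if (!identical(names(comp), ids))
      ke_alignment_error(
        "ensemble components carry different sample ids or orderings")
  }
  fused <- Reduce(`+`, lapply(components, as.numeric)) / length(components)
  score_vector(fused, ids, kind = "ensemble", normalized = TRUE)
}

#' Threshold decision rule
#'
#' Classifies each sample as unknown when its uncertainty score strictly
#' exceeds \eqn{\lambda}, and known otherwise (a score exactly equal to
#' \eqn{\lambda} is accepted as known).
#'
#' @param scores a [score_vector()] (or numeric vector named by sample).
#' @param lambda finite decision threshold.
#' @return A character vector (`"known"`/`"unknown"`) named by sample id.
#' @export
decide <- function(scores, lambda) {
  check_scalar_number(lambda, "lambda")
  v <- as.numeric(scores)
  out <- ifelse(v > lambda, "unknown", "known")
  names(out) <- names(scores)
  out
}
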