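#' Configuration of the synthetic open-set fixture generator
#'
#' Describes a seeded open-set recognition scenario: `k + u` class
#' centers on the unit sphere in `d` dimensions (minimum pairwise angular
#' separation enforced), observed in two feature spaces that share the
#' center layout but differ in noise — the "fine-tuned" space with
#' tighter clusters (`sigma_ft`) and the "pretrained" space with broader
#' noise (`sigma_pt`), emulating an encoder adapted to the task versus
#' its frozen original. Unknown-class centers are displaced away from the
#' known-center mass by `unknown_shift` before renormalization. Logits
#' are a linear-head surrogate: cosine similarity of fine-tuned test
#' features to the known centers times `logit_gain`. Text embeddings are
#' the known centers themselves.
#'
#' @param k number of known classes (>= 2).
#' @param u number of unknown classes (>= 1).
#' @param d embedding dimension (>= 2).
#' @param shots_train training bank rows per known class.
#' @param n_test_per_class test samples per class (known and unknown).
#' @param sigma_ft,sigma_pt per-coordinate Gaussian noise scale around
#'   each class center, in the fine-tuned and pretrained space.
#' @param separation minimum pairwise angle (radians) between class
#'   centers; a generation error is raised if unsatisfiable for
#'   `(k + u, d)`.
#' @param unknown_shift displacement magnitude applied to unknown
#'   centers, pushing them away from the mean of the known centers.
#' @param logit_gain scale of the surrogate linear head (sharp but not
#'   saturated softmax at the default 10).
#' @param seed integer master seed; center placement, bank noise and
#'   test noise use independent substreams so e.g. changing
#'   `n_test_per_class` does not perturb the centers.
#' @return An object of class `ke_synth_config`.
#' @export
synthetic_config <- function(k = 6L, u = 4L, d = 64L, shots_train = 16L,
                             n_test_per_class = 50L, sigma_ft = 0.05,
                             sigma_pt = 0.12, separation = pi / 6,
                             unknown_shift = 0.5, logit_gain = 10,
                             seed = 7L) {
  for (nm in c("k", "u", "d", "shots_train", "n_test_per_class", "seed")) {
    check_scalar_number(get(nm), nm)
    if (get(nm) != round(get(nm)))
      ke_parameter_error(sprintf("'%s' must be an integer", nm))
  }
  if (k < 2) ke_parameter_error("k must be >= 2")
  if (u < 1) ke_parameter_error("u must be >= 1")
  if (d < 2) ke_parameter_error("d must be >= 2")
  if (shots_train < 1) ke_parameter_error("shots_train must be >= 1")
  if (n_test_per_class < 1) ke_parameter_error("n_test_per_class must be >= 1")
  check_scalar_number(sigma_ft, "sigma_ft", positive = TRUE)
  check_scalar_number(sigma_pt, "sigma_pt", positive = TRUE)
  check_scalar_number(separation, "separation", positive = TRUE)
  check_scalar_number(logit_gain, "logit_gain", positive = TRUE)
  check_scalar_number(unknown_shift, "unknown_shift")
  if (unknown_shift < 0) ke_parameter_error("unknown_shift must be >= 0")
  structure(list(k = as.integer(k), u = as.integer(u), d = as.integer(d),
                 shots_train = as.integer(shots_train),
                 n_test_per_class = as.integer(n_test_per_class),
                 sigma_ft = sigma_ft, sigma_pt = sigma_pt,
                 separation = separation, unknown_shift = unknown_shift,
                 logit_gain = logit_gain, seed = as.integer(seed)),
            class = "ke_synth_config")
}

# Rejection-sample m unit vectors with pairwise angle >= separation.
sample_sphere_centers <- function(m, d, separation, max_attempts = 500L) {
  cos_max <- cos(separation)
  for (attempt in seq_len(max_attempts)) {
    c0 <- matrix(rnorm(m * d), nrow = m)
    c0 <- c0 / sqrt(rowSums(c0^2))
    g <- tcrossprod(c0)
    diag(g) <- -1
    if (max(g) <= cos_max) return(c0)
  }
  ke_generation_error(sprintf(
    "could not place %d centers in d=%d with pairwise angle >= %.3f rad",
    m, d, separation))
}

# Cluster samples: center + per-coordinate Gaussian noise, renormalized
# to the unit sphere.
noisy_cluster <- function(centers, class_idx, sigma) {
  d <- ncol(centers)
  x <- centers[class_idx, , drop = FALSE] +
    matrix(rnorm(length(class_idx) * d, sd = sigma), ncol = d)
  x / sqrt(rowSums(x^2))
}

#' Generate a complete synthetic open-set fixture
#'
#' Produces everything the scoring pipeline consumes: training feature
#' banks in both spaces (known classes only), test embeddings in both
#' spaces for known- and unknown-class samples, surrogate logits, text
#' embeddings (one per known class), the ground truth and the class
#' split. Fully deterministic given the configuration (which includes
#' the seed).
#'
#' @param config a [synthetic_config()].
#' @return An object of class `ke_bundle`: list with `bank_ft`,
#'   `bank_pt`, `test_feats_ft`, `test_feats_pt`, `test_logits`,
#'   `text_feats`, `truth`, `split`, `config`.
#' @examples
#' b <- generate_bundle(synthetic_config(k = 3, u = 2, d = 8,
#'                                       n_test_per_class = 5))
#' b$split
#' @export
generate_bundle <- function(config = synthetic_config()) {
  if (!inherits(config, "ke_synth_config"))
    ke_config_error("'config' must be a synthetic_config()")
  k <- config$k; u <- config$u; d <- config$d
  known_classes <- sprintf("known%02d", seq_len(k))
  unknown_classes <- sprintf("novel%02d", seq_len(u))
  classes <- c(known_classes, unknown_classes)

  centers <- withr::with_seed(
    derive_seed(config$seed, 1L),
    sample_sphere_centers(k + u, d, config$separation))
  if (config$unknown_shift > 0) {
    km <- colMeans(centers[seq_len(k), , drop = FALSE])
    for (j in (k + 1L):(k + u)) {
      w <- centers[j, ] - km
      wn <- sqrt(sum(w^2))
      if (wn > 0) {
        v <- centers[j, ] + config$unknown_shift * w / wn
        centers[j, ] <- v / sqrt(sum(v^2))
      }
    }
  }
  rownames(centers) <- classes

  # training banks: known classes only, shared row identity across spaces
  bank_class_idx <- rep(seq_len(k), each = config$shots_train)
  bank_ids <- sprintf("train_%s_%03d", known_classes[bank_class_idx],
                      sequence(rep(config$shots_train, k)))
  bank_x_ft <- withr::with_seed(
    derive_seed(config$seed, 2L),
    noisy_cluster(centers, bank_class_idx, config$sigma_ft))
  bank_x_pt <- withr::with_seed(
    derive_seed(config$seed, 3L),
    noisy_cluster(centers, bank_class_idx, config$sigma_pt))
  bank_ft <- feature_bank(
    embedding_matrix(bank_x_ft, "finetuned", bank_ids, l2_normalized = TRUE),
    known_classes[bank_class_idx])
  bank_pt <- feature_bank(
    embedding_matrix(bank_x_pt, "pretrained", bank_ids, l2_normalized = TRUE),
    known_classes[bank_class_idx])

  # test set: every class, known first
  test_class_idx <- rep(seq_len(k + u), each = config$n_test_per_class)
  n_test <- length(test_class_idx)
  test_ids <- sprintf("test_%04d", seq_len(n_test))
  test_x_ft <- withr::with_seed(
    derive_seed(config$seed, 4L),
    noisy_cluster(centers, test_class_idx, config$sigma_ft))
  test_x_pt <- withr::with_seed(
    derive_seed(config$seed, 5L),
    noisy_cluster(centers, test_class_idx, config$sigma_pt))
  test_feats_ft <- embedding_matrix(test_x_ft, "finetuned", test_ids,
                                    l2_normalized = TRUE)
  test_feats_pt <- embedding_matrix(test_x_pt, "pretrained", test_ids,
                                    l2_normalized = TRUE)

  # linear-head surrogate: cosine to known centers, scaled
  logits_vals <- config$logit_gain *
    tcrossprod(test_x_ft, centers[seq_len(k), , drop = FALSE])
  test_logits <- logit_matrix(logits_vals, test_ids, known_classes)

  text_feats <- text_embeddings(centers[seq_len(k), , drop = FALSE],
                                known_classes)

  truth <- ground_truth(
    test_ids,
    ifelse(test_class_idx <= k, "known", "unknown"),
    classes[test_class_idx])

  structure(list(
    bank_ft = bank_ft, bank_pt = bank_pt,
    test_feats_ft = test_feats_ft, test_feats_pt = test_feats_pt,
    test_logits = test_logits, text_feats = text_feats,
    truth = truth,
    split = open_set_split(known_classes, unknown_classes),
    config = config
  ), class = "ke_bundle")
}

#' Degrade exactly one information channel of a synthetic bundle
#'
#' Injects noise into a single channel so that the corresponding
#' ensemble component loses discriminative signal while the others stay
#' untouched — the fixture for studying component complementarity:
#' \describe{
#'   \item{`cpd`}{reassigns a `severity` fraction of logit rows among
#'     themselves (a seeded permutation), decoupling logits from sample
#'     identity.}
#'   \item{`dsk`}{blends fine-tuned test embeddings towards random unit
#'     vectors: `normalize((1 - severity) * x + severity * r)`.}
#'   \item{`gk`}{the same blend in the pretrained space.}
#' }
#' At `severity = 1` the degraded component's AUROC collapses to chance;
#' at `severity = 0` the bundle is returned unchanged. The degradation
#' RNG is a substream of the bundle's own seed, so repeated calls are
#' deterministic.
#'
#' @param bundle a [generate_bundle()] result.
#' @param component `"cpd"`, `"dsk"` or `"gk"`.
#' @param severity degradation strength in `[0, 1]`.
#' @return The modified `ke_bundle`.
#' @export
degrade_bundle <- function(bundle, component, severity) {
  if (!inherits(bundle, "ke_bundle"))
    ke_input_error("'bundle' must be a generate_bundle() result")
  if (!is.character(component) || length(component) != 1L ||
      !component %in% c("cpd", "dsk", "gk"))
    ke_parameter_error("component must be one of 'cpd', 'dsk', 'gk'")
  check_scalar_number(severity, "severity")
  if (severity < 0 || severity > 1)
    ke_parameter_error("severity must lie in [0, 1]")
  if (severity == 0) return(bundle)
  stream <- 100L + match(component, c("cpd", "dsk", "gk"))
  seed <- derive_seed(bundle$config$seed, stream)
  if (component == "cpd") {
    z <- bundle$test_logits$values
    n <- nrow(z)
    withr::with_seed(seed, {
      idx <- sample(n, size = round(severity * n))
      if (length(idx) > 1L) z[idx, ] <- z[sample(idx), , drop = FALSE]
    })
    bundle$test_logits <- logit_matrix(z, bundle$test_logits$sample_ids,
                                       bundle$test_logits$class_names)
  } else {
    slot <- if (component == "dsk") "test_feats_ft" else "test_feats_pt"
    emb <- bundle[[slot]]
    x <- emb$values
    withr::with_seed(seed, {
      r <- matrix(rnorm(length(x)), nrow = nrow(x))
    })
    r <- r / sqrt(rowSums(r^2))
    x <- (1 - severity) * x + severity * r
    x <- x / sqrt(rowSums(x^2))
    bundle[[slot]] <- embedding_matrix(x, emb$space_tag, emb$sample_ids,
                                       l2_normalized = TRUE)
  }
  bundle$degraded <- c(bundle$degraded, setNames(severity, component))
  bundle
}

#' Run the pipeline on a synthetic bundle
#'
#' Convenience wrapper: optionally subsamples the training banks to an
#' M-shot regime, then calls [run_knowledge_ensemble()] with the
#' bundle's own inputs.
#'
#' @param bundle a [generate_bundle()] result.
#' @param spec an [ensemble_spec()].
#' @param decision a [decision_config()].
#' @param shots a [shot_config()] applied to both banks, or `NULL` for
#'   the full banks.
#' @param temperature temperature for the CPD base score.
#' @return A `ke_result` (see [run_knowledge_ensemble()]).
#' @export
run_bundle <- function(bundle, spec = ensemble_spec("visual_three_way"),
                       decision = decision_config(), shots = NULL,
                       temperature = 1) {
  if (!inherits(bundle, "ke_bundle"))
    ke_input_error("'bundle' must be a generate_bundle() result")
  bank_ft <- bundle$bank_ft
  bank_pt <- bundle$bank_pt
  if (!is.null(shots)) {
    bank_ft <- few_shot_subsample(bank_ft, shots)
    bank_pt <- few_shot_subsample(bank_pt, shots)
  }
  run_knowledge_ensemble(
    test_feats_ft = bundle$test_feats_ft,
    test_feats_pt = bundle$test_feats_pt,
    bank_ft = bank_ft, bank_pt = bank_pt,
    truth = bundle$truth, test_logits = bundle$test_logits,
    text_feats = bundle$text_feats, spec = spec, decision = decision,
    temperature = temperature, split = bundle$split)
}

#' Sweep the generator and pipeline over a grid of configurations
#'
#' Maps [generate_bundle()] + [run_bundle()] over a list of
#' configurations (for example a few-shot ladder built by varying
#' `shots_train`, or an unknown-shift ramp) and collects one metrics row
#' per cell. Deterministic per cell via each configuration's own seed.
#'
#' @param configs list of [synthetic_config()] objects (possibly empty).
#' @param spec an [ensemble_spec()].
#' @param decision a [decision_config()].
#' @param temperature temperature for the CPD base score.
#' @return A data.frame with the generator parameters and
#'   `fpr_at_tpr95`, `auroc`, `accuracy_known` per configuration.
#' @export
sweep_protocol <- function(configs, spec = ensemble_spec("visual_three_way"),
                           decision = decision_config(), temperature = 1) {
  cols <- c("k", "u", "d", "shots_train", "n_test_per_class", "sigma_ft",
            "sigma_pt", "separation", "unknown_shift", "seed",
            "fpr_at_tpr95", "auroc", "accuracy_known")
  if (length(configs) == 0L) {
    out <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  rows <- lapply(configs, function(cfg) {
    if (!inherits(cfg, "ke_synth_config"))
      ke_config_error("every sweep cell must be a synthetic_config()")
    res <- run_bundle(generate_bundle(cfg), spec = spec, decision = decision,
                      temperature = temperature)
    data.frame(k = cfg$k, u = cfg$u, d = cfg$d,
               shots_train = cfg$shots_train,
               n_test_per_class = cfg$n_test_per_class,
               sigma_ft = cfg$sigma_ft, sigma_pt = cfg$sigma_pt,
               separation = cfg$separation,
               unknown_shift = cfg$unknown_shift, seed = cfg$seed,
               fpr_at_tpr95 = res$metrics$fpr_at_tpr95,
               auroc = res$metrics$auroc,
               accuracy_known = res$metrics$accuracy_known)
  })
  do.call(rbind, rows)
}
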