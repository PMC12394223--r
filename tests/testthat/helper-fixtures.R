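# Small fixture builders and independent oracles used across tests.

# Brute-force AUROC: exhaustive pair counting with half credit for ties.
auroc_pairwise <- function(known, unknown) {
  mean(outer(unknown, known, ">") + 0.5 * outer(unknown, known, "=="))
}

# Exhaustive threshold-sweep FPR oracle: every distinct score is a
# candidate lambda; pick the smallest achieving TPR >= level.
fpr_sweep_oracle <- function(known, unknown, level) {
  for (lam in sort(unique(c(known, unknown)))) {
    if (mean(known <= lam) >= level) return(mean(unknown <= lam))
  }
  stop("no candidate threshold reached the target TPR")
}

# Unit-basis embedding matrix: row i is the e_{idx[i]} basis vector in d
# dimensions (handy for constructing exact cosine similarities).
basis_embed <- function(idx, d, space = "finetuned", ids = NULL) {
  x <- matrix(0, nrow = length(idx), ncol = d)
  x[cbind(seq_along(idx), idx)] <- 1
  embedding_matrix(x, space_tag = space,
                   sample_ids = ids %||% paste0("q", seq_along(idx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Tiny hand-built open-set problem with perfect separation: two known
# classes on basis axes 1-2, unknowns on axis d.
separated_fixture <- function(d = 4) {
  bank <- feature_bank(basis_embed(c(1, 1, 2, 2), d, ids = paste0("tr", 1:4)),
                       c("a", "a", "b", "b"))
  bank_pt <- feature_bank(
    basis_embed(c(1, 1, 2, 2), d, space = "pretrained",
                ids = paste0("tr", 1:4)),
    c("a", "a", "b", "b"))
  test_ft <- basis_embed(c(1, 2, d, d), d, ids = paste0("te", 1:4))
  test_pt <- basis_embed(c(1, 2, d, d), d, space = "pretrained",
                         ids = paste0("te", 1:4))
  logits <- logit_matrix(10 * rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0)),
                         sample_ids = paste0("te", 1:4),
                         class_names = c("a", "b"))
  truth <- ground_truth(paste0("te", 1:4),
                        c("known", "known", "unknown", "unknown"),
                        c("a", "b", "z", "z"))
  list(bank_ft = bank, bank_pt = bank_pt, test_ft = test_ft,
       test_pt = test_pt, logits = logits, truth = truth)
}

small_config <- function(seed = 7, ...) {
  args <- list(k = 4, u = 2, d = 16, shots_train = 8, n_test_per_class = 25,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}
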