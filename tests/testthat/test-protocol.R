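test_that("split validation enforces disjoint, non-empty class sets", {
  expect_silent(validate_split(open_set_split(c("a", "b"), c("c", "d"))))
  err <- expect_error(validate_split(open_set_split(c("a", "b"), c("b", "c"))),
                      class = "ke_protocol_error")
  expect_match(conditionMessage(err), "\\bb\\b")
  expect_error(validate_split(open_set_split("a", character(0))),
               class = "ke_protocol_error")
  expect_error(validate_split(open_set_split(character(0), "a")),
               class = "ke_protocol_error")
})

make_bank <- function(k = 3, per_class = 10, d = 8, space = "finetuned",
                      seed = 1) {
  set.seed(seed)
  classes <- rep(paste0("c", seq_len(k)), each = per_class)
  feature_bank(
    embedding_matrix(matrix(rnorm(length(classes) * d), ncol = d), space,
                     sample_ids = paste0("t", seq_along(classes))),
    classes)
}

test_that("few-shot subsampling draws exactly M per class, deterministically", {
  bank <- make_bank()
  sub <- few_shot_subsample(bank, shot_config(2, seed = 42))
  expect_identical(as.integer(table(sub$classes)), rep(2L, 3))
  expect_identical(nrow(sub$embeddings$values), 6L)
  # determinism: same inputs, same seed, identical selection
  again <- few_shot_subsample(bank, shot_config(2, seed = 42))
  expect_identical(sub$embeddings$sample_ids, again$embeddings$sample_ids)
  expect_identical(sub$embeddings$values, again$embeddings$values)
  # shots = "all" returns the bank unchanged
  expect_identical(few_shot_subsample(bank, shot_config("all")), bank)
  # M larger than a class is a data error naming the class
  err <- expect_error(few_shot_subsample(bank, shot_config(11, seed = 1)),
                      class = "ke_data_error")
  expect_match(conditionMessage(err), "c1")
})

test_that("shot subsets are nested: 2-shot within 4-shot within 8-shot", {
  bank <- make_bank(per_class = 16)
  seeds <- c(3, 17, 99)
  for (seed in seeds) {
    prev <- character(0)
    for (m in c(2, 4, 8, 16)) {
      ids <- few_shot_subsample(bank, shot_config(m, seed))$embeddings$sample_ids
      expect_true(all(prev %in% ids))
      prev <- ids
    }
  }
})

test_that("the end-to-end run separates a hand-built open-set fixture", {
  fx <- separated_fixture()
  res <- run_knowledge_ensemble(
    test_feats_ft = fx$test_ft, test_feats_pt = fx$test_pt,
    bank_ft = fx$bank_ft, bank_pt = fx$bank_pt, truth = fx$truth,
    test_logits = fx$logits)
  expect_identical(res$metrics$auroc, 1)
  expect_identical(res$metrics$fpr_at_tpr95, 0)
  expect_identical(res$metrics$accuracy_known, 1)
  expect_identical(unname(res$decisions),
                   c("known", "known", "unknown", "unknown"))
  # every single component separates too on this fixture
  for (m in res$component_metrics) expect_identical(m$auroc, 1)
})

test_that("the VLM two-way ensemble is exactly the mean of dsk and gk", {
  fx <- separated_fixture()
  res <- run_knowledge_ensemble(
    test_feats_ft = fx$test_ft, test_feats_pt = fx$test_pt,
    bank_ft = fx$bank_ft, bank_pt = fx$bank_pt, truth = fx$truth,
    spec = ensemble_spec("vlm_two_way"))
  expect_equal(as.numeric(res$scores$ensemble),
               (as.numeric(res$scores$dsk) + as.numeric(res$scores$gk)) / 2,
               tolerance = 1e-15)
  expect_null(res$scores$cpd)
})

test_that("component metrics agree with metrics recomputed from exported scores", {
  b <- generate_bundle(small_config(sigma_ft = 0.3, sigma_pt = 0.4))
  res <- run_bundle(b)
  known <- b$truth$membership == "known"
  for (nm in names(res$component_metrics)) {
    s <- as.numeric(res$scores[[nm]])
    expect_identical(res$component_metrics[[nm]]$auroc,
                     auroc(s[known], s[!known]))
    expect_identical(res$component_metrics[[nm]]$fpr_at_tpr95,
                     fpr_at_tpr(s[known], s[!known], 0.95))
  }
})

test_that("banks containing unknown-class rows are rejected", {
  fx <- separated_fixture()
  # adversarial bank: an extra row labelled with an unknown class
  emb <- fx$bank_ft$embeddings
  poisoned <- feature_bank(
    embedding_matrix(rbind(emb$values, emb$values[1, ]), "finetuned",
                     c(emb$sample_ids, "evil")),
    c(fx$bank_ft$classes, "z"))
  err <- expect_error(
    run_knowledge_ensemble(test_feats_ft = fx$test_ft,
                           test_feats_pt = fx$test_pt,
                           bank_ft = poisoned, bank_pt = fx$bank_pt,
                           truth = fx$truth, test_logits = fx$logits),
    class = "ke_protocol_error")
  expect_match(conditionMessage(err), "z")
})

test_that("mode prerequisites are enforced", {
  fx <- separated_fixture()
  # visual mode with msp base but no logits
  expect_error(
    run_knowledge_ensemble(test_feats_ft = fx$test_ft,
                           test_feats_pt = fx$test_pt,
                           bank_ft = fx$bank_ft, bank_pt = fx$bank_pt,
                           truth = fx$truth),
    class = "ke_config_error")
  # vlm three-way needs text embeddings for the mcm base
  expect_error(
    run_knowledge_ensemble(test_feats_ft = fx$test_ft,
                           test_feats_pt = fx$test_pt,
                           bank_ft = fx$bank_ft, bank_pt = fx$bank_pt,
                           truth = fx$truth, test_logits = fx$logits,
                           spec = ensemble_spec("vlm_three_way")),
    class = "ke_config_error")
})

test_that("score histograms bin each membership group exactly", {
  ids <- paste0("s", 1:10)
  s <- score_vector(rep(0.1, 10), ids, kind = "ensemble", normalized = TRUE)
  truth <- ground_truth(ids, rep("known", 10), rep("a", 10))
  h <- export_score_distributions(s, truth, bins = 2)
  expect_identical(h$known, c(10L, 0L))
  expect_identical(h$unknown, c(0L, 0L))  # empty group: zero counts
  # uniform mid-point grid: exactly n/bins per bin
  ids2 <- paste0("g", 1:100)
  grid <- score_vector((seq_len(100) - 0.5) / 100, ids2, kind = "ensemble",
                       normalized = TRUE)
  truth2 <- ground_truth(ids2, rep(c("known", "unknown"), 50),
                         rep(c("a", "z"), 50))
  h2 <- export_score_distributions(grid, truth2, bins = 10)
  expect_identical(h2$known + h2$unknown, rep(10L, 10))
  expect_identical(sum(h2$known), 50L)
  expect_error(export_score_distributions(s, truth, bins = 1),
               class = "ke_parameter_error")
})
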