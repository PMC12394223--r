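test_that("max-logit score matches direct softmax evaluation in every dialect", {
  # uniform logits: softmax forced uniform, score -1/K
  expect_equal(as.numeric(max_logit_score(logit_matrix(rbind(c(0, 0, 0, 0))))),
               -0.25, tolerance = 1e-12)
  # oracle: direct softmax evaluation of the max class
  z <- c(3, 1, 0.5)
  expect_equal(as.numeric(max_logit_score(logit_matrix(rbind(z)))),
               -exp(3) / sum(exp(z)), tolerance = 1e-12)
  # temperature rescales before the softmax
  expect_equal(as.numeric(max_logit_score(logit_matrix(rbind(z)), temperature = 2)),
               -exp(1.5) / sum(exp(z / 2)), tolerance = 1e-12)
  # raw max logit is the identity on the row maximum
  expect_equal(as.numeric(max_logit_score(logit_matrix(rbind(c(1, 1))),
                                          dialect = "raw_maxlogit")), -1)
  # literal dialect: linear normalization without exponentials
  expect_equal(as.numeric(max_logit_score(logit_matrix(rbind(c(3, 1))),
                                          dialect = "literal")), -0.75)
})

test_that("max-logit rejects bad temperature and degenerate literal rows", {
  ml <- logit_matrix(rbind(c(1, 2)))
  expect_error(max_logit_score(ml, temperature = 0), class = "ke_parameter_error")
  expect_error(max_logit_score(ml, temperature = -1), class = "ke_parameter_error")
  zero_sum <- logit_matrix(rbind(c(1, -1)), sample_ids = "bad_row")
  err <- expect_error(max_logit_score(zero_sum, dialect = "literal"),
                      class = "ke_degenerate_error")
  expect_match(conditionMessage(err), "bad_row")
  expect_error(max_logit_score(logit_matrix(rbind(1))),
               class = "ke_input_error")  # msp needs K >= 2
})

test_that("energy score equals direct log-sum-exp evaluation", {
  expect_equal(as.numeric(energy_score(logit_matrix(rbind(c(0, 0))))),
               -log(2), tolerance = 1e-12)
  # single class: log exp identity gives the negated scaled logit exactly
  expect_identical(as.numeric(energy_score(logit_matrix(rbind(3.7)))), -3.7)
  expect_equal(as.numeric(energy_score(logit_matrix(rbind(5)), temperature = 2)),
               -2.5, tolerance = 1e-12)
  expect_equal(as.numeric(energy_score(logit_matrix(rbind(c(1, 2, 3))))),
               -log(exp(1) + exp(2) + exp(3)), tolerance = 1e-12)
  expect_error(energy_score(logit_matrix(rbind(1)), temperature = 0),
               class = "ke_parameter_error")
})

test_that("log-sum-exp implementation matches naive evaluation on bounded logits", {
  set.seed(11)
  for (i in 1:25) {
    z <- matrix(runif(12, -20, 20), nrow = 3)
    got <- as.numeric(energy_score(logit_matrix(z)))
    naive <- -log(rowSums(exp(z)))
    expect_equal(got, naive, tolerance = 1e-9)
  }
  # and it stays finite where the naive form overflows
  expect_true(is.finite(as.numeric(energy_score(logit_matrix(rbind(c(900, 901)))))))
})

test_that("mcm score is the negated max softmax over cosine similarities", {
  txt <- text_embeddings(diag(3), class_names = c("a", "b", "c"))
  # image on the first text axis: sims (1, 0, 0) -> -e/(e+2)
  img <- basis_embed(1, 3)
  expect_equal(as.numeric(mcm_score(img, txt)),
               -exp(1) / (exp(1) + 2), tolerance = 1e-12)
  # equidistant from all K concepts -> uniform softmax -> -1/K
  eq <- embedding_matrix(rbind(c(1, 1, 1)), "finetuned")
  expect_equal(as.numeric(mcm_score(eq, txt)), -1 / 3, tolerance = 1e-12)
  # K = 1: softmax over one class is 1 regardless of similarity
  one <- text_embeddings(rbind(c(0, 1, 0)), "only")
  expect_equal(as.numeric(mcm_score(img, one)), -1, tolerance = 1e-12)
  # errors: dimension mismatch, zero-norm row
  expect_error(mcm_score(basis_embed(1, 4), txt), class = "ke_input_error")
  expect_error(text_embeddings(rbind(c(0, 0, 0))), class = "ke_input_error")
})

test_that("knn dissimilarity is the negated max cosine over the bank", {
  bank <- feature_bank(basis_embed(1:2, 2, ids = c("b1", "b2")), c("a", "b"))
  # duplicate of a bank vector -> -1; oracle: exhaustive cosine
  q <- embedding_matrix(rbind(c(1, 0), c(0.6, 0.8)), "finetuned")
  s <- knn_dissimilarity(q, bank)
  expect_equal(as.numeric(s), c(-1, -0.8), tolerance = 1e-12)
  expect_identical(attr(s, "kind"), "dsk")
  # orthogonal to every bank vector -> 0
  bank3 <- feature_bank(basis_embed(1:2, 3, ids = c("b1", "b2")), c("a", "b"))
  expect_equal(as.numeric(knn_dissimilarity(basis_embed(3, 3), bank3)), 0,
               tolerance = 1e-12)
  # raw values bounded in [-1, 1] on random inputs
  set.seed(4)
  rq <- embedding_matrix(matrix(rnorm(40), 10), "finetuned")
  rb <- feature_bank(embedding_matrix(matrix(rnorm(20), 5), "finetuned"),
                     rep("a", 5))
  expect_true(all(abs(as.numeric(knn_dissimilarity(rq, rb))) <= 1 + 1e-12))
  # mixing model spaces is a protocol error
  bank_pt <- feature_bank(basis_embed(1:2, 2, space = "pretrained"), c("a", "b"))
  expect_error(knn_dissimilarity(q, bank_pt), class = "ke_protocol_error")
})

test_that("min-max normalization rescales, keeps ranks, and handles degeneracy", {
  s <- score_vector(c(1, 2, 3), kind = "energy")
  expect_equal(as.numeric(minmax_normalize(s)), c(0, 0.5, 1))
  expect_equal(as.numeric(minmax_normalize(score_vector(c(5, 5), kind = "energy"))),
               c(0.5, 0.5))
  expect_equal(as.numeric(minmax_normalize(score_vector(c(-1, 1), kind = "energy"))),
               c(0, 1))
  # rank invariance on random draws
  set.seed(9)
  for (i in 1:10) {
    v <- rnorm(20)
    n <- minmax_normalize(score_vector(v, kind = "energy"))
    expect_identical(order(as.numeric(n)), order(v))
  }
  # frozen statistics: deployment mode clamps into [0, 1]
  froz <- minmax_normalize(score_vector(c(-2, 0.5, 7), kind = "energy"),
                           stats = c(0, 1))
  expect_equal(as.numeric(froz), c(0, 0.5, 1))
  expect_true(attr(froz, "normalized"))
})

test_that("cpd score normalizes the chosen base over the evaluated set", {
  base <- score_vector(c(-0.9, -0.5, -0.1), kind = "energy")
  expect_equal(as.numeric(cpd_score(base = base)), c(0, 0.5, 1))
  expect_identical(attr(cpd_score(base = base), "kind"), "cpd")
  const <- score_vector(c(-0.3, -0.3), kind = "energy")
  expect_equal(as.numeric(cpd_score(base = const)), c(0.5, 0.5))
  # symmetric two-sample logits: equal msp maxima -> both map to 0.5
  lg <- logit_matrix(rbind(c(2, 0), c(0, 2)))
  expect_equal(as.numeric(cpd_score(lg, method = "msp")), c(0.5, 0.5))
  # mcm base without text embeddings is a configuration error
  expect_error(cpd_score(lg, method = "mcm"), class = "ke_config_error")
  expect_error(cpd_score(method = "energy"), class = "ke_config_error")
})

test_that("dsk and gk components are normalized knn scores in their own spaces", {
  bank_ft <- feature_bank(basis_embed(1:2, 3, ids = c("b1", "b2")), c("a", "b"))
  bank_pt <- feature_bank(basis_embed(1:2, 3, space = "pretrained",
                                      ids = c("b1", "b2")), c("a", "b"))
  # one duplicate + one orthogonal sample -> raw (-1, 0) -> normalized (0, 1)
  q_ft <- basis_embed(c(1, 3), 3)
  d <- dsk_score(q_ft, bank_ft)
  expect_equal(as.numeric(d), c(0, 1))
  expect_identical(attr(d, "kind"), "dsk")
  q_pt <- basis_embed(c(1, 3), 3, space = "pretrained")
  g <- gk_score(q_pt, bank_pt)
  expect_equal(as.numeric(g), c(0, 1))
  expect_identical(attr(g, "kind"), "gk")
  # all duplicates -> all raw -1 -> degenerate 0.5
  expect_equal(as.numeric(dsk_score(basis_embed(c(1, 2), 3), bank_ft)),
               c(0.5, 0.5))
  # space tags enforced
  expect_error(dsk_score(q_pt, bank_pt), class = "ke_protocol_error")
  expect_error(gk_score(q_ft, bank_ft), class = "ke_protocol_error")
})

test_that("ensemble fusion is the element-wise mean with aligned, normalized inputs", {
  mk <- function(v, kind) score_vector(v, paste0("s", seq_along(v)),
                                       kind = kind, normalized = TRUE)
  three <- list(mk(0.2, "cpd"), mk(0.4, "dsk"), mk(0.6, "gk"))
  expect_equal(as.numeric(ensemble_score(three, ensemble_spec("visual_three_way"))),
               0.4)
  expect_equal(as.numeric(ensemble_score(list(mk(0.3, "dsk"), mk(0.5, "gk")),
                                         ensemble_spec("vlm_two_way"))), 0.4)
  # idempotence on identical components
  v <- c(0.1, 0.7, 0.4)
  same <- list(mk(v, "cpd"), mk(v, "dsk"), mk(v, "gk"))
  expect_equal(as.numeric(ensemble_score(same, ensemble_spec())), v)
  # invariant to component order within a mode
  expect_equal(as.numeric(ensemble_score(rev(three), ensemble_spec())),
               as.numeric(ensemble_score(three, ensemble_spec())))
  # unnormalized component is a protocol error
  raw <- score_vector(0.2, "s1", kind = "cpd", normalized = FALSE)
  expect_error(ensemble_score(list(raw, mk(0.4, "dsk"), mk(0.6, "gk")),
                              ensemble_spec()), class = "ke_protocol_error")
  # sample-id mismatch is an alignment error, never a silent reorder
  flipped <- score_vector(c(0.4, 0.2), c("s2", "s1"), kind = "dsk",
                          normalized = TRUE)
  expect_error(ensemble_score(list(mk(c(0.2, 0.4), "cpd"), flipped,
                                   mk(c(0.1, 0.2), "gk")), ensemble_spec()),
               class = "ke_alignment_error")
  # kinds must match the mode
  expect_error(ensemble_score(list(mk(0.3, "dsk"), mk(0.5, "gk")),
                              ensemble_spec("visual_three_way")),
               class = "ke_protocol_error")
})

test_that("ensemble fusion is permutation-equivariant in samples", {
  set.seed(21)
  ids <- paste0("s", 1:8)
  mk <- function(v, kind) score_vector(v, ids, kind = kind, normalized = TRUE)
  comps <- list(mk(runif(8), "cpd"), mk(runif(8), "dsk"), mk(runif(8), "gk"))
  fused <- ensemble_score(comps, ensemble_spec())
  perm <- sample(8)
  comps_p <- lapply(comps, function(s)
    score_vector(as.numeric(s)[perm], ids[perm], kind = attr(s, "kind"),
                 normalized = TRUE))
  fused_p <- ensemble_score(comps_p, ensemble_spec())
  expect_equal(as.numeric(fused_p), as.numeric(fused)[perm])
})

test_that("decision rule: unknown strictly above lambda, known at or below", {
  s <- score_vector(c(0.2, 0.9), c("a", "b"), kind = "ensemble",
                    normalized = TRUE)
  expect_identical(unname(decide(s, 0.5)), c("known", "unknown"))
  # boundary: score exactly lambda is known
  expect_identical(unname(decide(s, 0.9)), c("known", "known"))
  # lambda at the maximum score accepts everything
  expect_true(all(decide(s, max(as.numeric(s))) == "known"))
  expect_error(decide(s, Inf), class = "ke_parameter_error")
})

test_that("duplicating a bank sample never scores above an orthogonal one", {
  # direction convention on constructed fixtures across score kinds
  d <- 6
  bank <- feature_bank(basis_embed(1:3, d, ids = paste0("b", 1:3)),
                       c("a", "b", "c"))
  q <- basis_embed(c(1, d), d)  # duplicate, then orthogonal-to-all
  raw <- as.numeric(knn_dissimilarity(q, bank))
  expect_lt(raw[1], raw[2])
  txt <- text_embeddings(diag(d)[1:3, ], class_names = c("a", "b", "c"))
  m <- as.numeric(mcm_score(q, txt))
  expect_lt(m[1], m[2])
})
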