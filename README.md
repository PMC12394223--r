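# knowens

Post-hoc **knowledge-ensemble uncertainty scoring** for open-set
recognition, aimed at plant-disease image classification where disease
categories unseen during training appear at test time and must be
rejected rather than silently assigned to a known class.

## The problem and the method

A classifier trained on known classes `K = {c_1, …, c_k}` faces test
samples from both `K` and a disjoint set of unknown classes `U`
(`K ∩ U = ∅`). Open-set recognition attaches to every test sample `x_i`
an uncertainty score `S(x_i)` — higher means more anomalous — and decides

```
unknown  if S(x_i) > λ,      known  if S(x_i) ≤ λ.
```

Single post-hoc scores read only one information channel of the model
and degrade badly in few-shot regimes. `knowens` fuses three channels,
each min-max normalized to [0, 1] over the evaluated test set:

- **S_CPD** — category prediction distribution: a base score on the
  fine-tuned classifier head, `−max softmax(z/T)` (MSP; raw max-logit
  and a linear-normalization dialect are selectable) or the energy score
  `−log Σ_i exp(z_i/T)`; for vision-language models, maximum concept
  matching `−max softmax(sim(f, g_i)/T)` over per-class text embeddings.
- **S_DSK** — domain-specific knowledge: negated maximum cosine
  similarity between the test embedding and a training feature bank,
  both in the *fine-tuned* encoder's space.
- **S_GK** — general knowledge: the same matching in the *frozen
  pretrained* encoder's space, which retains the general structure that
  fine-tuning can overwrite.

The ensemble is a non-parametric mean:

```
S = (S_CPD + S_DSK + S_GK) / 3     (CNN / ViT frameworks)
S = (S_DSK + S_GK) / 2             (vision-language models)
```

Evaluation follows the standard open-set protocol with knowns as the
positive class: **FPR@TPR95** (fraction of unknowns accepted at the
threshold that keeps ≥ 95% of knowns), **AUROC** (probability an
unknown outscores a known, half credit for ties) and **closed-set
accuracy** on the known classes.

The package is purely post hoc: it consumes logits and embeddings
exported from your models (TSV matrices + a JSON manifest) and never
trains anything. A seeded synthetic generator provides open-set
fixtures with the geometry the method assumes, so the whole stack runs
and is tested fully offline.

## Worked example

```r
library(knowens)

cfg <- synthetic_config(k = 4, u = 2, d = 32, shots_train = 8,
                        n_test_per_class = 30, sigma_ft = 0.3,
                        sigma_pt = 0.4, seed = 11)
bundle <- generate_bundle(cfg)
res <- run_bundle(bundle, spec = ensemble_spec("visual_three_way"))
res
#> <ke_result> mode=visual_three_way components={cpd, dsk, gk}
#> final: <ke_metrics> n_known=120 n_unknown=60
#>   FPR@TPR95 = 0.2000   AUROC = 0.9640   accuracy(known) = 0.9500
#>   lambda = 0.510143   achieved TPR = 0.9500
#>   confusion: TP=114 FN=6 FP=12 TN=48
#>   cpd  AUROC = 0.9019  FPR@TPR95 = 0.4667
#>   dsk  AUROC = 0.9129  FPR@TPR95 = 0.4833
#>   gk   AUROC = 0.7951  FPR@TPR95 = 0.6500
```

Read: at the threshold λ = 0.51 accepting 95% of known samples, 20% of
unknowns slip through; the fused score separates the groups better
(AUROC 0.964) than any single channel (0.90 / 0.91 / 0.80) — the
complementarity the ensemble exploits. The per-group score histogram is
a numeric export:

```r
export_score_distributions(res$scores$ensemble, bundle$truth, bins = 5)
#>   bin lower upper known unknown
#> 1   1   0.0   0.2     8       0
#> 2   2   0.2   0.4    75       1
#> 3   3   0.4   0.6    34      18
#> 4   4   0.6   0.8     3      35
#> 5   5   0.8   1.0     0       6
```

## Command line

A thin wrapper over the same functions (installed at
`system.file("cli", "knowens", package = "knowens")`):

```sh
knowens simulate --seed 7 --out fixture/          # write a TSV+manifest fixture
knowens evaluate --config fixture/ --out results/ # scores.tsv, report.json,
                                                  # component_metrics.json, histogram.tsv
knowens sweep    --seed 7 --shots 2,4,8,16 --out results/   # few-shot ladder
```

Exit codes: 0 success, 2 validation/usage error, 1 internal error.

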