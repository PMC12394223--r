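---
title: "Knowledge-ensemble uncertainty scoring: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-ensemble uncertainty scoring: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knowens)
```

## The open-set problem

A plant-disease classifier is trained on known classes
$K = \{c_1,\dots,c_k\}$, possibly with only $M$ images per class
(few-shot). At deployment it also meets samples from unknown classes
$U$, disjoint from $K$. The task is twofold: classify known samples
correctly, and *reject* unknown ones. Rejection is driven by an
uncertainty score $S(x_i)$ — higher means more anomalous — and a
threshold rule: a sample is declared unknown iff $S(x_i) > \lambda$
(equality is accepted as known).

## Three knowledge channels

Fine-tuning buys domain-specific discrimination at the cost of the
general visual knowledge stored in the pretrained encoder. Each model
therefore offers three complementary views of a test sample, and the
package scores each:

1. **Category prediction distribution (CPD).** A base score on the
   fine-tuned classification head. The default is the negative maximum
   softmax probability $-\max_i \mathrm{softmax}(z/T)_i$; alternatives
   are the raw negative max logit, the energy score
   $-\log\sum_i e^{z_i/T}$, and — for vision-language models — maximum
   concept matching, the same softmax form over cosine similarities
   between the image embedding and per-class text embeddings.
2. **Domain-specific knowledge (DSK).** Negated maximum cosine
   similarity between the test embedding and the training feature bank,
   both computed by the *fine-tuned* encoder. Known-class samples land
   near the bank and score low.
3. **General knowledge (GK).** The same nearest-neighbour matching in
   the *frozen pretrained* encoder's space, recovering the broad visual
   structure that fine-tuning may have overwritten and thereby
   calibrating the fine-tuned model's overconfidence, especially in
   few-shot regimes.

Each channel is min-max normalized to $[0,1]$ and the ensemble is their
plain mean: $(S_{CPD}+S_{DSK}+S_{GK})/3$ for purely visual frameworks,
$(S_{DSK}+S_{GK})/2$ for vision-language models (whose text-driven
confidence is unreliable for fine-grained disease symptoms; the
three-way variant with MCM as the CPD base is available as
`vlm_three_way` for comparison). No weights are learned; the fusion is
deliberately non-parametric.

### On the max-logit dialects

The linear form $-\max_i (z_i/T)/\sum_j (z_j/T)$ is undefined whenever
the scaled logits sum to zero and flips sign for negative sums, so it
cannot serve as a safe default for arbitrary classifier heads. The
package defaults to the softmax form (`msp`), which preserves the
ranking intent and matches the structure of the concept-matching score;
`raw_maxlogit` and the `literal` linear form remain selectable, the
latter raising a degenerate-input error naming any zero-sum row.

## Normalization conventions

`Norm(·)` is min-max over the full set of scores being evaluated
together — a transductive choice: the test set is scored jointly, as in
batch evaluation of a monitoring system. Each component carries its own
normalization; min/max statistics are never shared across components.
For single-sample deployment, `minmax_normalize(scores, stats =)`
accepts statistics frozen on a calibration set and clamps into $[0,1]$.
Two properties matter:

- min-max scaling is strictly increasing, so it changes no ranking and
  leaves AUROC exactly invariant (asserted numerically in the tests);
- when a component is constant (`max == min`) it maps to 0.5
  everywhere, contributing nothing to the ensemble ranking rather than
  poisoning it with NaNs.

Embeddings are L2-normalized internally before every cosine
computation; all-zero rows are rejected at construction with the row
named, since cosine similarity is undefined there.

## Evaluation protocol

Knowns are the positive class. With $n$ known scores and target TPR
level $t$ (default 0.95), the threshold is the $\lceil t\,n\rceil$-th
smallest known score — the smallest order statistic guaranteeing
$\mathrm{TPR} \ge t$; with small $n$ the achieved TPR can overshoot and
is reported alongside. FPR@TPR95 is then the fraction of unknowns at or
below the threshold. AUROC uses the rank-based Mann–Whitney form with
half credit for ties, matching its interpretation as the probability
that an unknown sample outscores a known one; the tests verify exact
agreement with brute-force pair counting. Samples scoring exactly
$\lambda$ are accepted as known, consistently with the decision rule.
Closed-set accuracy is measured on known-labelled samples only, with
predictions by argmax over logits (or over image–text similarity when
only text embeddings are available).

## The synthetic generator

`generate_bundle()` emulates the separability premise of the method —
known test samples near the training features, unknown samples farther,
in both spaces — without any image data:

- $k+u$ class centers are drawn uniformly on the unit sphere in $d$
  dimensions, redrawn until every pairwise angle is at least
  `separation` (default $\pi/6$; unsatisfiable configurations raise a
  generation error rather than degrading silently).
- Both feature spaces share the center layout (that is the correlation
  between them); samples are centers plus per-coordinate Gaussian noise,
  renormalized to the sphere. The fine-tuned space is tighter
  (`sigma_ft = 0.05`) than the pretrained one (`sigma_pt = 0.12`),
  mimicking an encoder adapted to the task versus its frozen original.
- Unknown centers are pushed away from the mean of the known centers by
  `unknown_shift` (default 0.5), so separability is a monotone dial.
- Logits are a linear-head surrogate: cosine similarity of the
  fine-tuned test features to the known centers, scaled by
  `logit_gain = 10` — sharp but not saturated softmax. Text embeddings
  are the known centers themselves.
- One master seed drives center placement, bank noise and test noise
  through independent substreams, so changing the test-set size does
  not move the centers, and regeneration is byte-identical.

Defaults — 6 known and 4 unknown classes, $d = 64$, 16-shot banks, 50
test samples per class (500 total) — depict a clean, moderately sized
16-shot benchmark; under them every channel separates nearly perfectly,
as clean-data benchmarks do in the many-shot regime. Noisier settings
(e.g. `sigma_ft = 0.3`) expose the regime where the channels disagree
and fusion pays off. `degrade_bundle()` manufactures that regime
surgically: it destroys exactly one channel (permuting a fraction of
logit rows across samples, or blending one space's test embeddings
toward random unit vectors) while leaving the other channels untouched,
enabling the complementarity checks in the test suite.

What the generator does *not* emulate: real image statistics, class
imbalance, label noise, background/illumination variation, or the
fine-grained visual similarity between a healthy leaf and its diseased
counterpart. Passing tests therefore certify the *scoring and
evaluation machinery* — directions, identities, protocol arithmetic,
determinism — not field performance on real plant imagery.

## Few-shot protocol

`few_shot_subsample()` draws $M$ rows per known class (presets 2, 4, 8,
16, or `all`) by a seeded per-class shuffle with prefix selection, so
shot subsets are nested ($2 \subset 4 \subset 8 \subset 16$) and
ablation curves move for one reason only. The similarity banks under an
$M$-shot setting are built from the same $M$-shot subset that would
have fine-tuned the model, since the few-shot regime redefines the
training set; banks are validated to contain known classes only, and a
class with fewer than $M$ rows raises an error naming it.

## Numerical choices and degenerate inputs

- Energy and softmax scores use the log-sum-exp trick; agreement with
  naive evaluation is within $10^{-9}$ for $|z| \le 20$ and the stable
  form stays finite where the naive form overflows.
- TSV serialization uses 17 significant digits, so
  `read(write(x))` reproduces doubles bit-exactly; fixtures regenerate
  byte-identically under a fixed seed.
- Score fusion aligns components by sample id and refuses mismatched
  ids or orders — never a silent reorder. Unnormalized components are
  refused likewise.
- Ties in prediction argmax break toward the first class — relevant
  only for exactly tied logits.
- The problem sizes used in the test suite (mostly $k=4, u=2, d=16$,
  a few hundred samples; 200-instance oracle sweeps with $n \le 50$)
  keep the whole suite in the tens of seconds while still exercising
  ties, degeneracies and the statistical trend checks over ten seeds.

## Known limitations

- The transductive normalization couples a sample's score to the batch
  it is evaluated with; use frozen statistics for online deployment.
- The ensemble weights are fixed and equal; when one channel is
  systematically uninformative the mean dilutes the informative ones
  (the degradation tests bound, but do not remove, this effect).
- AUROC and FPR@TPR95 are threshold-set metrics over a single score
  dimension; per-class open-set behaviour (which unknown classes leak
  in) is visible only through the exported score tables.
- The generator's clusters are isotropic Gaussians on the sphere; real
  embedding manifolds are anisotropic and multi-modal.
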