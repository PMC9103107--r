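---
title: "Contrastive pre-training for motif occupancy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contrastive pre-training for motif occupancy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`motifclr` predicts whether fixed-length DNA motif instances are bound
by a transcription factor. This vignette documents the statistical
machinery, the choices made where the design was genuinely open, and
what the synthetic benchmarks do and do not establish.

## Sequence similarity

All similarity computation rests on the Needleman–Wunsch global
alignment score with Match = 1 and Mismatch = Indel = 0, with a zero
boundary row and column. Under this parameterization the score is the
length of the longest common subsequence (LCS): matches are the only way
to accumulate score, and gaps are free. `nw_score()` implements the
score-only dynamic program (two rolling rows, C++); no traceback is
kept because only `F[L][L]` is ever used, so tie-breaking between
co-optimal alignment paths never arises. The test suite checks the DP
against `lcs_oracle()`, an exhaustive subsequence enumerator that shares
no code with it.

`sequence_similarity()` divides by the common length, giving a value in
[0, 1] that is 1 exactly for identical sequences and 0 exactly when the
two sequences share no token types.

**The null token.** `N` (unknown base) one-hot-encodes to the zero row,
but in the similarity it matches itself: `char_match()` is literal
equality. The alternative — treating `N` as matching nothing — is
available via `n_matches_n = FALSE`, but literal equality is the
default because the similarity criterion is defined on characters, not
on their encodings, and augmented views deliberately introduce `N`s that
should count as agreement between sibling views.

## Edit augmentation

`augment_pair()` derives two views from one sequence. Each view receives
`k` edits, `k` uniform on `{1, …, floor(0.05·L)}` (so at most 5 for
L = 101). Three length-preserving operations are used, the drawn kind
uniform over the three (their relative frequency is a free choice; the
uniform mix keeps all three well exercised):

* **insertion + deletion**: a random token from `{A,C,G,T}` is inserted
  at a uniform position, then one character of the lengthened sequence
  is deleted at a uniform position — the insertion is paired with a
  deletion precisely so the length never changes;
* **substitution**: one position is replaced by a *different* token
  (a no-op substitution would silently shrink the effective edit count);
* **deletion-to-null**: one position is replaced by `N`.

A single substitution or null-deletion can lower the inter-view LCS by
at most 1 and an insertion+deletion pair by at most 2, so the edit
budget keeps sibling views similar; since the worst-case bound under two
5-op programs is weaker than the desired floor, the pair is checked
post hoc and fully resampled (both views, fresh ops) while
`xsim ≤ 0.9`, up to 100 retries. Resampling rather than repairing keeps
the output distribution easy to reason about. In practice the floor is
rarely hit: the observed minimum over 1,000 default augmentations is
91/101 ≈ 0.9010, exactly one LCS unit above the floor.

## Pair labeling

Over the `2n` views of a batch (`make_batch_views()`, ordered
x₁¹, x₁², …, xₙ¹, xₙ²), `build_pair_labels()` produces a symmetric
matrix with entries positive / negative / neutral:

* **editclr** — thresholds on the similarity *of the augmented views
  themselves* (not their origins): positive above 0.8, negative below
  0.7, neutral in between. Boundary values are neutral: both
  inequalities are strict, and a pair sitting exactly on a threshold
  belongs to the band whose evidence is weakest. Sibling views are
  always positive because augmentation guarantees similarity > 0.9.
  Published variants of the thresholds disagree (one formulation uses
  0.7/0.4); the pair (0.8, 0.7) chosen by the interval statistics is the
  default, and `threshold_preset()` exposes the no-neutral variants
  `editCLR-0.7` and `editCLR-0.8` (positive threshold equal to
  negative) used as comparators.
* **supclr** — positive iff the origin records share the occupancy
  label; neutral never occurs.
* **simclr** — sibling views positive, all other pairs negative;
  similarity is never computed.

The editclr labeling costs O(n²L²) per batch — all C(2n, 2) pairwise
similarities — which is why that kernel is compiled.

## Loss functions

Both losses operate on cosine similarities of the 64-dimensional pooled
encoder outputs, divided by a temperature τ. For view *a* with positive
set *P*, negative set *N*, and *A* = all 2n − 1 other views:

* self-supervised:
  `L_a = −(|P|+|N|)/(|A||P|) Σ_{p∈P} log[ exp(s_ap/τ) / Σ_{q∈P∪N} exp(s_aq/τ) ]`.
  Neutral pairs appear in neither numerator nor denominator. The leading
  scale compensates for the variable sizes of P and N so each view's
  contribution stays within the scale of a single-positive-pair loss
  (with it, the degenerate single-positive labeling reduces exactly to
  NT-Xent).
* supervised:
  `L_a = −(1/|P|) Σ_{p∈P} log[ exp(s_ap/τ) / Σ_{q∈A} exp(s_aq/τ) ]`,
  denominator over all other views.

Conventions for degenerate inputs: a view with `|P| = 0` contributes 0
(the 1/|P| scale is undefined and there is nothing to attract); cosine
similarity with a zero-norm embedding is defined as 0 (global max
pooling of an all-nonpositive feature map yields the zero vector, e.g.
for an all-`N` input with non-positive biases). Both losses use
log-sum-exp stabilization (subtract the row maximum) and are always
non-negative because each positive term's numerator is one summand of
its denominator. Analytic gradients are verified against central finite
differences at 1e−5 tolerance, and vectorized loss values against naive
double-loop references at 1e−10.

## Architecture and training

The encoder is a single valid convolution (kernel 24, 64 kernels,
stride 1, biases) over the L×4 one-hot input — window count
L − 24 + 1 = 78 for L = 101 — followed by ReLU and per-channel global
max pooling. ReLU is used because the architecture family this encoder
follows (DeepBind/DeepSEA-style motif scanners) rectifies after
convolution; valid rather than same padding keeps every window fully
inside the sequence. Max-pool ties break to the first window, which
matters only for gradient routing, not the forward value. The
classifier is 64 → 32 (ReLU) → dropout → 2, softmax. Weights are
Glorot-uniform from a seeded stream; biases start at zero. There is no
projection head: the contrastive loss is applied to the pooled code
directly, so what is pre-trained is exactly what the classifier
consumes.

Pre-training minimizes the contrastive loss with Adam
(β₁ = 0.9, β₂ = 0.999, weight decay as classic L2) for at most 5
epochs, batch size n = 1024 by default, and returns the final epoch
(no selection signal exists without labels). The learning rate is
`α·√n`: square-root batch scaling is the published convention for
contrastive pre-training, and `α` defaults to 0.001 — the low end of
the log grid {0.001, …, 0.5} over which it is searchable, appropriate
for the self-supervised variant. An explicit `learning_rate` overrides
the rule. Trailing batches with fewer than 2 records are dropped (no
pairs exist).

Fine-tuning trains encoder and classifier jointly with 2-class
cross-entropy (identical to binary cross-entropy over a 2-unit softmax)
at learning rate and weight decay 0.001, batch 128, at most 20 epochs,
and returns the epoch with the highest accuracy on a held-out 1/8
validation split — validation, not training, accuracy, and never the
test set. `train_baseline()` is the same routine started from fresh
encoder weights, sharing every architectural hyper-parameter, so the
comparison isolates the effect of pre-training. `grid_search()`
enumerates dropout {0.1, 0.25, 0.5}, τ {1.0, 0.1, 0.01}, α and
weight-decay log grids exhaustively and reports every combination's
validation accuracy; the search can be run per dataset or once
globally, whichever the analysis calls for.

Determinism: every stochastic stage (splits, shuffling, augmentation,
dropout, initialization) draws from R's Mersenne-Twister via an
explicit seed in its config, restoring the caller's RNG state
afterwards, so whole pipelines are bit-reproducible in single-threaded
runs. Checkpoints are plain JSON at full double precision with the
config embedded.

## Evaluation

`evaluate()` thresholds the predicted binding probability at 0.5 for
the confusion table; precision, recall and `F1 = TP/(TP + (FP+FN)/2)`
(algebraically the harmonic mean of P and R), with zero-denominator
cases reported as 0 with a warning. AUC is the trapezoid under the
threshold-swept ROC staircase with tied scores collapsed, which equals
the normalized Mann–Whitney U statistic — the test suite asserts this
equality and agreement with pROC. A single-class test set has no ROC:
AUC is `NA` with a warning.

## Synthetic data: what it does and does not show

`generate_motif_dataset()` plants one mutated copy of an 8-mer consensus
(default `TGACGTCA`, a CREB/AP-1-like palindrome) at a uniform offset in
uniform background for positives; negatives are pure background. Class
balance is exact; mutation flips each motif position to a different
token with probability 0.1 by default. Mean similarity between random
background pairs concentrates near 0.62, reproducing the concentration
of real motif-instance pairs in the 0.5–0.7 similarity band that
motivates treating that band as negative.

What passing on this generator shows: the losses, labeling, gradients,
optimizer and selection logic are correct and the pipeline can extract
a planted, localized signal. What it does not show: performance on real
ChIP-seq data, where binding signals are degenerate (PWM-like, multiple
sites per sequence), background is not uniform (GC content, repeats),
and labels are noisy. The generator deliberately omits PWM sampling,
GC matching and dinucleotide shuffles to keep the signal geometry
analyzable: a single planted site makes the substring-scan oracle
(`motif_scan_scores()`) a known-answer classifier with AUC ≈ 1 at zero
mutation, anchoring the evaluation code independently of any trained
model.

The package's own benchmark sizes are 2,000 training and 500 test
records with mutation 0.1, pre-training batch 256: large enough that
baseline, editCLR and supCLR pipelines all exceed test AUC 0.85 with
the default epoch caps, small enough to run routinely on one CPU. At
these sizes pre-training is 40 Adam steps — a scale at which editCLR and
supCLR improve over the baseline's AUC but the three remain within a few
points, so the synthetic benchmark validates mechanics, not the ranking
of the methods at production scale.

## Known limitations

* Batch size 1024 with editclr labeling computes ~2M alignments per
  step; the C++ kernel sustains this, but very large pre-training runs
  remain alignment-bound (the documented O(n²L²) cost). Faster
  similarity estimation is out of scope.
* Only the two single-layer encoder widths (64, 128 kernels) are
  provided; deeper variants, Bayesian CNNs and gkm-SVM comparators are
  out of scope.
* Input sequences must share one length per dataset; no genome
  coordinates or BED handling — the pipeline operates on pre-extracted
  motif-instance windows.
* Hard pair labels only; soft similarity-valued labels are a possible
  extension, not implemented.
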