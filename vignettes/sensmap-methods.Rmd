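---
title: "Cross-study transfer learning for drug sensitivity: models and design choices"
author: "sensmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-study transfer learning for drug sensitivity: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Large pharmacogenomic screens profile gene expression and drug response
(summarized as the area under the dose-response curve, AUC) across panels of
cancer cell lines. Two screens rarely agree: expression measured on
different platforms is highly rank-concordant but shifted gene by gene,
while response measurements are only weakly concordant across laboratories.
`sensmap` addresses the practical situation in which a *target* study has
drug response for only a small subset of its cell lines (a few dozen),
while a *source* study has full response data over the same cell lines and
genes. The goal is to predict the target study's missing AUC values by
borrowing strength from the source study instead of training on the small
labeled subset alone.

Two method families are implemented, plus the baselines needed to judge
them.

## Latent-variable cost optimization

Write `y11` for the target AUC over the `n1` labeled training cells and
`y21` for the matched source AUC over the same cells. Both are modeled as
affine functions of one unobserved latent signal `w1`, itself a convex
combination of the two observed vectors:

    w1 = c0 + c1 * y11 + c2 * y21,   -1 <= c0 <= 1,
                                      0 <= c1, c2 <= 1,  c1 + c2 = 1.

For a candidate weight vector, each study vector is reconstructed from the
design `W1 = [1 w1]` by inner least squares (`y11 ~ W1 a1`,
`y21 ~ W1 a2`), and the weights are chosen to minimize the ratio cost

    ( ||y11 - W1 a1||^2 + ||y21 - W1 a2||^2 ) /
    ( rho(y11, w1) + rho(y21, w1) )

with `rho` the Pearson correlation: good latents reconstruct both studies
well *and* are strongly positively concordant with each. The formulation
presumes the two studies move in the same direction; when no convex
combination is positively concordant with both vectors the optimization
reports failure rather than returning a sign-flipped latent.

Three predictors build on this:

* **LRP (Latent Regression Prediction).** The latent is regressed on the
  source response (`w1 ~ [1 y21] b2`, fitted by the Moore-Penrose
  pseudoinverse so a rank-deficient design degrades gracefully). For
  prediction cells the latent is inferred from their source AUC,
  `w2 = [1 y22] b2`, and mapped to the target scale with the stored
  reconstruction coefficients, `y12 = [1 w2] a1`. Only response data is
  used; matched source AUC is required for every prediction cell.
* **LLP (Latent-Latent Prediction).** The same constrained optimization is
  run gene by gene on the paired expression columns, and the per-gene
  latents are concatenated into an n-by-p matrix `V`. A regressor (random
  forest by default) learns `V[train] -> w1`; the predicted latent for the
  remaining cells yields `y12` through `a1` as before. Prediction needs no
  source AUC for the unlabeled cells, so LLP applies to unmatched pairs.
* **CLP (Combined Latent Prediction).** The LRP and LLP latents for each
  prediction cell are averaged before mapping through `a1`. Both arms share
  a single cost optimization, hence identical reconstruction coefficients.
  Like LRP it requires matched source AUC.

### Design choices in the optimization

The objective is provably flat in the offset `c0`: the reconstruction
designs carry an intercept column, and Pearson correlation is
shift-invariant. `c0` is therefore fixed at 0, and the search is
one-dimensional over `t = c1` in `[0, 1]` with `c2 = 1 - t`. The solver
scans a 1001-point uniform grid and then refines around the best grid point
with bounded scalar minimization (tolerance `1e-10`); both stages evaluate
the objective through a closed-form identity in the second moments
(the residual sum of squares of a simple regression is
`(n-1) var(u) (1 - r^2)`), which is algebraically identical to the
definitional objective and keeps the per-gene latent construction fast.
Squared correlations are clamped at 1 so exactly collinear inputs yield a
cost of exactly zero rather than a roundoff-negative value. On flat
stretches of the objective the returned weight is the feasible `t` closest
to 0.5 (equal weighting of the two studies), and a refinement step is
accepted only when it improves the cost beyond roundoff so the tie-break is
not overridden by noise. The correlation-sum denominator is floored at
`1e-8`; points at or below the floor are infeasible. The single-study
regression coefficient `b1` (latent on target response) plays no role in
prediction and is not computed by default.

A degenerate gene column (zero variance in either study) cannot be
optimized; its latent falls back to the standardized mean of the two
columns, the gene is flagged, and the rest of the matrix proceeds.

## Domain-transfer (Mapped Prediction)

The second family models the between-study relationship directly with
polynomial maps:

* **Gene-wise first-order map.** For each gene `i`, ordinary least squares
  of the source-space expression on `[1, g_target,i]`. The per-gene
  intercepts and slopes are the diagonals of the affine map
  `G_hat = 1 A0 + G A1`. First order suffices because cross-study
  expression is highly rank-concordant; the per-gene Spearman correlation
  is reported as a diagnostic rather than used to switch orders
  automatically, since no principled threshold exists.
* **Drug-wise second-order map.** Target AUC regressed on
  `[1, d_source, d_source^2]`. Response concordance is much weaker and the
  relationship between studies' AUC scales is curved, hence the quadratic.
  The fit is plain OLS; a warning is emitted when the fitted parabola's
  vertex falls inside the observed source range (a non-monotone map
  contradicts the same-direction assumption). Mapped values are not clipped
  to `[0, 1]`; out-of-range predictions are reported.

**Mapped Prediction (MP)** composes them: fit the gene map target-to-source
and the drug map source-to-target on the labeled cells; map the unlabeled
target expression into source space; score it with a model trained on the
*full* source study; map the source-space predictions back to the target
AUC scale. The directions matter and are covered by a dedicated test. By
default the gene map is fitted on the labeled training cells only (the
labeled subset is what the matched design guarantees); fitting on all
matched cells is available as an option since expression, unlike response,
is usually available for unlabeled cells too.

The default source model is a **bias-corrected random forest (BC-RF)**.
Random-forest regression compresses predictions toward the response mean;
the correction fits a simple linear regression of the training response on
the out-of-bag predictions and applies the stored slope and intercept to
every raw forest output. The linear-in-OOB correction is the simplest
member of the published bias-correction family and is isolated behind the
regressor handle so other variants can be swapped in. Forest defaults are
conventional for regression: 500 trees, features-per-split `ceiling(p/3)`,
minimum node size 5, and an explicit seed so repeated fits are identical.

## Feature selection

`relieff_rank()` implements RReliefF, the regression variant of ReliefF:
features are weighted by how strongly their differences track response
differences among nearest neighbors (10 by default), with
distance-weighted neighbor contributions, range-normalized Manhattan
distances, and all instances used deterministically (no sampling). Ties are
broken by feature identifier. `select_intersection()` takes the top-k
genes of each study's ranking (k = 200 conventionally) and intersects
them, giving a feature set relevant in both studies.

## Evaluation protocol

`make_folds()` partitions the n cells into `K = floor(n / 50)` near-equal
random folds (the remainder is spread one cell per fold). The protocol
*inverts* the usual cross-validation orientation: each fold in turn is the
small training set and the union of the other `K - 1` folds is the test
set, emulating the data-poor target study. Metrics are Pearson correlation
and NRMSE, computed per fold and averaged (not pooled). NRMSE is RMSE
divided by the range of the true test values; since more than one
normalization is in circulation, the convention is recorded in every
report. Baselines: **DP** trains on the labeled target cells only; **CP**
trains on the full source study and predicts from raw (unmapped) target
expression; **CMP** trains one model on the concatenation of the full
source study and the labeled target cells. The benchmark runner enforces
applicability — LRP and CLP are skipped, with the reason logged, on studies
lacking matched source AUC for the prediction cells — and embeds seeds and
settings in the report.

## The synthetic paired-study generator

All validation runs on `generate_paired_study()`, which emulates the
matched two-study setting:

1. target expression is standard normal (the methods are unit-agnostic, so
   standardized log-like values lose no generality);
2. source expression is a per-gene affine image of it — slopes drawn from
   `[0.7, 1.3]`, intercepts from `[-3, 3]` — plus Gaussian noise with SD
   0.55. The noise level puts the median per-gene cross-study Spearman
   correlation near 0.86, the concordance regime reported for matched
   expression in large screens; the wide intercept range represents the
   large gene-level location shifts of un-harmonized platforms and is
   invisible to rank-based concordance;
3. a latent response signal is carried by a small set of marker genes
   (3 by default, as for targeted agents) plus optional noise, then
   standardized;
4. each study's AUC is affine in the latent, or — when a quadratic map
   `beta` is supplied — the source AUC is affine in the latent and the
   target AUC is its quadratic image, mirroring the curved between-study
   response relationship;
5. AUC vectors that stray outside `[0, 1]` are min-max squashed toward
   `[0.02, 0.98]`, affinely, so noiseless-recovery identities survive the
   squash; the offending fraction is reported.

The generator returns the ground truth (latent, map coefficients, marker
genes) for recovery tests. What it deliberately does *not* emulate: the
severe response discordance of real screens (real matched AUC vectors
correlate far more weakly than two noisy affine images of one latent can),
assay-specific heavy tails and censoring at the AUC boundaries, batch
structure within a study, and non-affine expression distortions. Passing
tests therefore demonstrate internal correctness and the expected ordering
of methods under the generative assumptions the methods themselves make —
not performance on any particular real study pair.

## Problem sizes and numerical conventions

The test suite and the acceptance script use studies of 300 cells by 100
genes with 50-cell training folds for the benchmark regimes, 200-cell
studies for the recovery fixtures, and 20-30 observations for the solver
oracles; these sizes make every property checkable in seconds while
keeping the training-fold-to-study ratio of the motivating design.
Reduced tree counts (300) are used where a forest is refitted many times.
Degenerate inputs follow a uniform policy: constant vectors where a
correlation is needed raise a typed error; constant gene columns in maps
get slope 0 and intercept at the mean with a warning; a constant source
response in the latent regression is handled by the pseudoinverse with a
warning; an all-infeasible grid raises an optimization error.

## Known limitations

The latent family assumes positive concordance between the paired response
vectors; anti-correlated studies are rejected rather than re-signed. The
quadratic drug map is fitted unregularized on as few as 50 points and can
be non-monotone (warned, not corrected). The per-gene latent matrix is
rebuilt per benchmark fold; for matched designs it depends only on the
expression matrices, and callers running many folds over identical
matrices can construct it once with `build_gene_latents()` and pass a
custom regressor pipeline instead. Only two studies are supported — no
multi-source latents — and IC50-scale response is out of scope.
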