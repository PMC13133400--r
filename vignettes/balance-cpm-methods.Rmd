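---
title: "Methods: connectome-based prediction of balance performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based prediction of balance performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Standing balance in older adults is a whole-brain skill: it draws on motor,
subcortical, visual and attentional systems simultaneously. balanceCPM asks
whether an individual's balance performance can be *predicted* from their
brain connectome — the node-by-node matrix of connection strengths derived
from resting-state functional MRI (functional connectome, Fisher-z
correlation units) or from diffusion tractography (structural connectome,
streamline counts normalized by node volume). The behavioral target is the
posturographic sway area: the area of the 95% confidence ellipse covering
the center-of-pressure (COP) trajectory recorded on a force plate, in cm²,
where smaller areas mean better balance.

The package starts at matrices: image acquisition, registration,
parcellation and tractography are upstream and out of scope. A typical
input is one square symmetric matrix per subject and modality on a
268-node parcellation grouped into ten canonical networks, plus a cohort
table with the behavior score and covariates.

## The sway-area metric

For a COP trajectory with 2×2 sample covariance having eigenvalues
$\lambda_1, \lambda_2$, the package computes

$$\mathrm{Area} = \pi \cdot c \cdot \sqrt{\lambda_1 \lambda_2},$$

with two selectable constants. The `as_printed` variant uses
$c = \sqrt{\chi^2_{0.95,2}} = 2.4478$, the constant as it conventionally
appears in the posturography literature. The `chi2_standard` variant uses
$c = \chi^2_{0.95,2} = 5.9915$, which is the dimensionally standard 95%
confidence-ellipse area (the quantile multiplies the variance product, not
its square root). The two differ by the exact factor 2.4478; because the
published convention applies the constant once, `as_printed` is the
default, and every `sway_area()` result records which variant produced it.
The covariance uses the unbiased $n-1$ denominator by default. When a
measurement comprises several trials, the balance score is the *minimum*
(best) trial area; a single trial is accepted.

## The CPM model

`cpm()` implements connectome-based predictive modeling with leave-one-out
cross-validation (LOOCV). For each fold, with subject $i$ held out:

1. **Edgewise association.** For every upper-triangle edge, the partial
   Spearman correlation between edge weight and behavior is computed on the
   $N-1$ training subjects. All variables (edge, behavior, covariates) are
   rank-transformed with average ranks on ties; ranked edge and ranked
   behavior are residualized on the ranked covariates by least squares, and
   the statistic is the Pearson correlation of the residuals. Two-sided
   p-values use the t approximation with $df = n - 2 - k$ for $k$
   covariates. Age and sex (coded 0/1) are the default covariates; extras
   such as mean framewise displacement can be added.
2. **Selection.** Edges with $p < t$ are kept and split by correlation
   sign: the *positive network* (weights rise with sway area) and the
   *negative network* (weights fall with sway area, i.e. rise with balance
   ability). Each sign is modeled separately.
3. **Summary scores.** Each training subject's selected edge weights are
   summed into a single number per modality.
4. **Fit and predict.** Behavior is regressed on the summary score(s) by
   ordinary least squares, and the held-out subject is predicted from
   their own summary over the fold's mask.

Model quality is the Spearman correlation $\rho$ between the $N$ pooled
predictions and the observed scores (Pearson is available for sensitivity
analysis). Because selection is repeated inside every fold, the held-out
subject's behavior can influence neither their own edge mask nor their
prediction — a property the test suite checks exactly.

A fold whose mask is empty predicts the training mean (with a warning), so
all $N$ predictions stay defined; a fit where *every* fold is empty is an
error. With both modalities requested, selection runs per modality at the
shared threshold and the two summary scores enter one two-slope
regression; rank-deficient designs fall back to minimum-norm least squares
with a collinearity warning.

## Threshold selection

The selection threshold is searched over a grid from 0.0001 to 0.05 in
steps of 0.0001. The stated selection principle — highest prediction
accuracy while maintaining stability, with stability judged by the
variance of the prediction effect size across nearby thresholds — is
under-determined at a grid of step 0.0001 (each interval holds one point),
so the package implements it as a sliding-window rule: the stability of a
threshold is the variance of the LOOCV $\rho$ over its centered window of
`window = 5` grid neighbors, a threshold is eligible when its window
variance is at or below the `quantile = 0.5` (median) of all window
variances, and the eligible threshold with the highest $\rho$ wins, ties
broken toward the smaller threshold. Both parameters are configurable and
the full $\rho$-versus-threshold table is returned for inspection. If no
threshold is eligible the global maximum is used with a warning.

## Significance and multiplicity

`permutation_test()` shuffles the correspondence between behavior and
connectomes B = 1000 times (derived deterministically from one master
seed) and reruns the complete LOOCV — including within-fold feature
selection — at the model's fixed threshold after each shuffle. Two
decisions are deliberate: the threshold is **not** re-optimized inside
permutations (the shuffle tests the model configuration as built, and
re-searching would multiply cost several hundredfold), and covariates are
**not** permuted (the shuffle severs only the behavior-connectome link,
leaving the covariate-connectome pairing intact). The raw p-value is the
printed counting rule, the fraction of null correlations ≥ the observed
one; since this can be exactly 0, the positively biased but never-zero
add-one estimator $(k+1)/(B+1)$ is co-reported. A degenerate permutation
in which every fold is empty scores $\rho = -1$ rather than being dropped,
keeping the null size exactly B. Across the model families (modality ×
sign, typically four), raw permutation p-values are adjusted by the
Benjamini–Hochberg step-up procedure (`bh_fdr()`, backed by
`stats::p.adjust` and cross-checked in the tests against a brute-force
oracle).

## Consensus connectomes and network summaries

Edges selected in *all* LOOCV folds form the consensus connectome — the
reported predictive network. `network_distribution()` summarizes it by
canonical network; since the denominator behind published percentage
breakdowns of this kind is not standardized, two labeled conventions are
provided: `endpoint` (default; an edge adds one count to each endpoint
network, one count total when both endpoints share a network) and
`within_double` (a within-network edge counts twice, making proportions
pure endpoint shares). `node_degree_table()` ranks nodes by consensus
degree with ties broken by node index.

## External validation, specificity, and frozen coefficients

`finalize_model()` freezes the consensus mask and refits the coefficients
on all training subjects using consensus-mask summary scores. That
full-sample refit is the package's reading of "the model estimated at
timepoint 1": which coefficients travel to external data is genuinely
open, and the refit was chosen because it uses all available training
information on exactly the edge set being exported (per-fold coefficient
averaging was the considered alternative). `external_validate()` then
scores an external cohort — e.g. repeat-measurement data three months
later — from its own connectomes through the frozen mask and
coefficients; the external behavior is used only for the final
correlation, never for fitting, so shuffling it changes $\rho$ but not a
single prediction. External p-values are parametric (Spearman
t-approximation), not permutation-based. `specificity_test()` applies the
same mechanics with an unrelated behavior (rate of torque development, a
strength measure) as the target: a balance-specific model should track it
at chance level.

## Structural connectome normalization

The node-volume normalization formula used by tractography pipelines is
configuration-dependent, so the package makes it explicit:
`volume_normalize()` defaults to $c_{ij}/(v_i + v_j)$ (size-additive,
contact-surface rationale) with $c_{ij}/\sqrt{v_i v_j}$ and
$c_{ij}/\bar v$ selectable; the rule applied is always recorded in the
output's provenance attribute.

## The synthetic-data generator

`simulate_cohort()` produces the test substrate for every stage. Each
subject carries a latent balance trait $z \sim N(0,1)$; sway area is the
strictly increasing, right-skewing transform $20\exp(0.5\,\ell)$ of
$\ell = -z + 0.3c + \varepsilon$ ($c$ the combined standardized age/sex
covariate, $\varepsilon$ noise with sd 0.2), so a larger trait means a
smaller sway area. A planted subset of functional edges loads on $z$ with
target correlation `effect_size` and signs half positive, half negative —
so both the positive- and negative-network code paths carry real signal.
Structural edges share the planted positions, agree with the functional
sign with probability `sc_fc_coupling = 0.8`, and pass through an
exponential link, giving non-negative heavy-tailed weights. Every edge
also receives a small random covariate loading, so partialing is
exercised. Timepoint 2 is a correlated redraw $x_2 = r x_1 +
\sqrt{1-r^2}\,\mathrm{noise}$ at `retest_reliability = 0.7`, and the
secondary behavior is drawn independently of $z$.

Defaults emulate the target study design: 54 subjects, 48 retested, 42
with the strength measure, age ~ N(71, 4.8²), sex balanced. The default
geometry is 60 nodes (1770 edges) rather than 268 (35,778): this keeps a
full fit-permute-validate cycle to a few seconds so that the multi-seed
test batteries (20-seed parameter recovery, 100-seed specificity, 200-rep
permutation calibration) complete in minutes; `preset = "paper_scale"`
restores the 268-node geometry. What the generator does *not* emulate:
realistic connectome topology (modularity, small-worldness, distance
effects), spatially structured noise, site or scanner effects, and
non-monotone brain-behavior relationships. Passing tests therefore
demonstrate that the estimator recovers the planted generative structure
under calibrated noise — not that real connectomes predict real balance.

## Numerical choices and degenerate inputs

* Connectomes must arrive symmetric to a relative tolerance of 1e-6;
  `(M + M^T)/2` is applied below it, above it is an error, never a silent
  fix. Diagonals are zeroed on ingest.
* Zero-variance edges get $\rho = 0$, $p = 1$ (never selected); constant
  covariates are dropped with a warning; constant behavior is an error.
* Upper-triangle vectorization is column-major (R's `upper.tri` order);
  node indices are 1-based everywhere user-facing, linear edge positions
  are internal.
* Spearman evaluation p-values use the t approximation uniformly
  (`cor.test(..., exact = FALSE)`), so tied predictions are handled
  consistently.
* All randomness (generator, permutations) derives from explicit seeds
  through isolated RNG streams that restore global state.

## Limitations

The LOOCV evaluation correlation is an optimistic estimator when the
threshold is tuned on the same data — the permutation test, which holds
the search fixed, is the honest significance instrument here. Only linear
single- or two-predictor models are implemented (no regularization,
k-fold, or nested CV), matching the method being modeled. The consensus
network-percentage conventions are reporting choices, not statistics with
sampling theory attached.
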