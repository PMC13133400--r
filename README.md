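# balanceCPM

Connectome-based predictive modeling (CPM) of postural balance from
structural and functional brain connectomes, in R.

## What it is for

Balance control in older adults engages distributed brain systems, and a
natural question is whether an individual's balance performance can be
predicted from their brain network alone. balanceCPM implements the full
CPM analysis for that question, starting from matrices (no image
processing): per-subject symmetric connectome matrices — functional
(Fisher-z correlations of resting fMRI time series) and/or structural
(tractography streamline counts normalized by node volume) — plus a
cohort table with the behavioral score and covariates. The behavioral
target is the posturographic **sway area**: the 95% confidence-ellipse
area of the center-of-pressure trajectory in cm²,

    Area = π · 2.4478 · √(λ₁ λ₂),

with λ₁, λ₂ the eigenvalues of the COP sample covariance (smaller area =
better balance; the dimensionally standard variant with χ²₀.₉₅,₂ = 5.9915
in place of its square root is also provided).

The core estimator is CPM with leave-one-out cross-validation. In each
fold, every edge's **partial Spearman correlation** with behavior
(age and sex partialled out on ranks) is computed on the training
subjects; edges with p < t are kept and split by sign into a positive
network (correlated with sway area) and a negative network
(anti-correlated with sway area, hence aligned with balance ability);
each training subject's selected edge weights are summed to a single
summary score; behavior is regressed on the summary score by OLS; and the
held-out subject is predicted from their own summary. Model quality is
Spearman's ρ between pooled predictions and observed scores. The
threshold t is searched over 0.0001–0.05 with a stability-aware rule,
significance comes from a permutation test (B = 1000 full LOOCV reruns
under shuffled behavior) with Benjamini–Hochberg correction across the
model families, and edges surviving every fold form the **consensus
connectome**, summarized by canonical brain network and node degree.
Frozen consensus models support test–retest validation on a second
timepoint and specificity tests against an unrelated behavior (strength:
rate of torque development).

A fully synthetic cohort generator with planted edge–behavior effects,
covariate confounding, structure–function coupling and a correlated
second timepoint ships with the package and backs the test suite.

## Worked example

```r
library(balanceCPM)

sim <- simulate_cohort(cohort_spec(seed = 42))   # 54 subjects, 60 nodes
fit <- cpm(sim$tp1, modality = "functional", sign = "negative",
           threshold = 0.01)
fit
#> CPM fit: negative network, modality functional
#>   n = 54 subjects, p-threshold = 0.01
#>   LOOCV spearman rho = 0.749 (parametric p = 7.564e-11)
#>   consensus edges: functional 16

permutation_test(fit, sim$tp1, B = 200, seed = 43)
#> Permutation test: observed rho = 0.749, B = 200
#>   p (count/B) = 0; p (add-one) = 0.004975

external_validate(fit, sim$tp2)      # frozen model on the retest timepoint
#> External validation (primary behavior): rho = 0.652, p = 5.141e-07, n = 48

specificity_test(fit, sim$tp1)       # unrelated behavior: chance level
#> External validation (secondary behavior): rho = 0.047, p = 0.7656, n = 42
```

The LOOCV ρ of 0.75 says the cross-validated predictions rank subjects'
sway areas well; the permutation p confirms this exceeds every one of 200
shuffled-behavior reruns; the retest ρ of 0.65 shows the frozen consensus
model transfers to second-timepoint connectomes; and the specificity ρ of
0.05 shows it does not predict the independent strength score.
`summary(fit)` adds the consensus connectome's network breakdown (here
dominated by subcortical and motor connections, as planted) and top-degree
nodes; `plot(fit)` draws predicted-vs-observed and the
ρ-versus-threshold curve when a search was run. `run_pipeline()` chains
all four families (modality × sign), permutation tests, BH correction,
consensus mapping and validation from one config list or YAML file.

Threshold search instead of a fixed cutoff: `cpm(..., threshold = NULL)`
(grid 0.0001–0.05, sliding-window stability rule; see the methods
vignette in `vignettes/balance-cpm-methods.Rmd`).

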