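#' Permutation test of CPM significance
#'
#' Shuffles the correspondence between behavior and connectomes `B` times;
#' after each shuffle the *entire* LOOCV — including within-fold feature
#' selection — is rerun at the model's fixed threshold and the evaluation
#' correlation recorded, giving the null distribution. Covariates stay
#' paired with their subjects (only the behavior-connectome correspondence
#' is broken), and the threshold is not re-optimized inside permutations.
#' The raw p-value is the fraction of null correlations greater than or
#' equal to the observed one (`count/B`); the never-zero add-one estimator
#' `(count+1)/(B+1)` is co-reported.
#'
#' A permutation in which every fold has an empty edge mask scores
#' correlation -1 (kept, so the null size is exactly `B`); the tally is
#' reported.
#'
#' @param fit a [cpm()] fit (supplies threshold, sign, modalities,
#'   covariates, and the observed evaluation correlation).
#' @param cohort the training [cpm_cohort()] the fit was estimated on.
#' @param B number of permutations (default 1000; minimum 100).
#' @param seed master seed; all permutations derive from it
#'   deterministically.
#' @return Object of class `cpm_perm`: `observed_rho`, `null_rhos`
#'   (length `B`), `p_raw`, `p_add_one`, `n_degenerate`, `B`, `seed`.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 16, n_nodes = 12,
#'                                    n_planted = 6, seed = 3))
#' fit <- cpm(sim$tp1, threshold = 0.05)
#' pt <- permutation_test(fit, sim$tp1, B = 100, seed = 1)
#' pt$p_raw
#' @export
permutation_test <- function(fit, cohort, B = 1000L, seed = 1L) {
  stopifnot(inherits(fit, "cpm"), inherits(cohort, "cpm_cohort"))
  B <- as.integer(B)
  if (B < 100L) stop("B must be at least 100 (null too coarse below that)")
  n <- n_subjects(cohort)
  y <- cohort$behavior
  rng <- local_rng(seed)
  Yperm <- vapply(seq_len(B), function(b) y[sample.int(n)], numeric(n))
  restore_rng(rng)
  folds <- cpm_folds(cohort, fit$modalities, fit$covariates)
  run <- loocv_core(cohort, folds, fit$modalities, Yperm, fit$threshold,
                    fit$sign)
  null_rhos <- vapply(seq_len(B), function(b) {
    if (run$empty[b] == n) -1
    else eval_cor(run$preds[, b], Yperm[, b], fit$eval)
  }, numeric(1L))
  k <- sum(null_rhos >= fit$rho)
  structure(list(observed_rho = fit$rho, null_rhos = null_rhos,
                 p_raw = k / B, p_add_one = (k + 1) / (B + 1),
                 n_degenerate = sum(run$empty == n), B = B, seed = seed),
            class = "cpm_perm")
}

#' @export
print.cpm_perm <- function(x, ...) {
  cat(sprintf("Permutation test: observed rho = %.3f, B = %d\n",
              x$observed_rho, x$B))
  cat(sprintf("  p (count/B) = %.4g; p (add-one) = %.4g\n",
              x$p_raw, x$p_add_one))
  if (x$n_degenerate)
    cat(sprintf("  %d degenerate permutations scored rho = -1\n",
                x$n_degenerate))
  invisible(x)
}

# seed an isolated RNG stream and return the previous global state
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Benjamini-Hochberg adjustment across model families
#'
#' Step-up false-discovery-rate correction applied across the families of
#' model tests (here typically four: functional/structural x
#' positive/negative). Delegates to [stats::p.adjust()] and preserves
#' names and input order.
#'
#' @param p_values numeric vector of raw p-values in \[0, 1\] (optionally
#'   named by family).
#' @return Adjusted p-values, same order and names.
#' @examples
#' bh_fdr(c(fp = 0.016, fn = 0.016, sp = 0.17, sn = 0.17))
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::setNames(stats::p.adjust(p, method = "BH"), names(p_values))
}
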