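#' Run the full CPM analysis pipeline
#'
#' Orchestrates the end-to-end analysis for a set of model families
#' (modality x network sign): threshold selection (or a fixed threshold),
#' leave-one-out cross-validated prediction, permutation significance,
#' Benjamini-Hochberg correction *across* the families, consensus-connectome
#' extraction with network summaries, and optional combined-modality,
#' external-validation and specificity stages.
#'
#' The configuration is a named list (or a path to a YAML file with the
#' same structure):
#' \describe{
#'   \item{families}{list of lists with `modality` (character vector) and
#'     `sign`; default the four single-modality families.}
#'   \item{threshold}{`NULL` to search (default), or a fixed cutoff, or a
#'     list `search = list(lo, hi, step, window, quantile)`.}
#'   \item{covariates}{character vector, default `c("age", "sex")`.}
#'   \item{permutations}{list `B` (default 1000) and `seed`.}
#'   \item{evaluation}{`"spearman"` (default) or `"pearson"`.}
#'   \item{validate_external, specificity}{logical switches.}
#' }
#'
#' @param cohort training [cpm_cohort()].
#' @param config named list or YAML path (see Details).
#' @param external optional external [cpm_cohort()] for test-retest
#'   validation.
#' @return List of class `cpm_report`: per-family results (`fit`, `perm`,
#'   `p_raw`, `p_corrected`, consensus summaries), plus `validation` and
#'   `specificity` entries where requested, and the resolved `config`.
#' @export
run_pipeline <- function(cohort, config = list(), external = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- list(
    families = list(list(modality = "functional", sign = "positive"),
                    list(modality = "functional", sign = "negative"),
                    list(modality = "structural", sign = "positive"),
                    list(modality = "structural", sign = "negative")),
    threshold = NULL,
    covariates = c("age", "sex"),
    permutations = list(B = 1000L, seed = 1L),
    evaluation = "spearman",
    validate_external = !is.null(external),
    specificity = !is.null(cohort$secondary))
  # shallow override: user keys replace defaults wholesale (families is an
  # unnamed list, which modifyList would silently skip)
  for (nm in names(config)) cfg[[nm]] <- config[[nm]]

  thr_arg <- cfg$threshold
  fams <- list()
  for (fam in cfg$families) {
    key <- paste(paste(fam$modality, collapse = "+"), fam$sign, sep = "_")
    message("fitting family: ", key)
    fit <- if (is.numeric(thr_arg))
      cpm(cohort, fam$modality, fam$sign, threshold = thr_arg,
          covariates = cfg$covariates, eval = cfg$evaluation)
    else if (is.list(thr_arg) && !is.null(thr_arg$search))
      cpm(cohort, fam$modality, fam$sign, threshold = NULL,
          covariates = cfg$covariates, eval = cfg$evaluation,
          grid = seq(thr_arg$search$lo, thr_arg$search$hi,
                     by = thr_arg$search$step),
          window = thr_arg$search$window %||% 5L,
          quantile = thr_arg$search$quantile %||% 0.5)
    else
      cpm(cohort, fam$modality, fam$sign, threshold = NULL,
          covariates = cfg$covariates, eval = cfg$evaluation)
    perm <- permutation_test(fit, cohort, B = cfg$permutations$B,
                             seed = cfg$permutations$seed)
    fams[[key]] <- list(fit = fit, perm = perm, p_raw = perm$p_raw,
                        threshold = fit$threshold, rho = fit$rho,
                        consensus_size = vapply(fit$consensus, length,
                                                integer(1L)),
                        networks = lapply(fit$consensus, function(e)
                          if (length(e)) network_distribution(e, cohort$atlas)))
  }
  p_raw <- vapply(fams, `[[`, numeric(1L), "p_raw")
  p_corr <- bh_fdr(p_raw)
  for (key in names(fams)) fams[[key]]$p_corrected <- p_corr[[key]]

  report <- list(families = fams, p_raw = p_raw, p_corrected = p_corr,
                 config = cfg)
  if (isTRUE(cfg$validate_external) && !is.null(external)) {
    report$validation <- lapply(fams, function(fm)
      if (!is.null(fm$fit$coefficients))
        external_validate(fm$fit, external))
  }
  if (isTRUE(cfg$specificity) && !is.null(cohort$secondary)) {
    report$specificity <- lapply(fams, function(fm)
      if (!is.null(fm$fit$coefficients))
        tryCatch(specificity_test(fm$fit, cohort),
                 error = function(e) NULL))
  }
  class(report) <- "cpm_report"
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cpm_report <- function(x, ...) {
  cat("CPM pipeline report\n")
  for (key in names(x$families)) {
    fm <- x$families[[key]]
    cat(sprintf("  %-24s thr=%.4g rho=%+.3f p_raw=%.4g p_BH=%.4g consensus=%s\n",
                key, fm$threshold, fm$rho, fm$p_raw, fm$p_corrected,
                paste(fm$consensus_size, collapse = "/")))
  }
  if (!is.null(x$validation)) {
    cat("external validation (test-retest):\n")
    for (key in names(x$validation))
      if (!is.null(x$validation[[key]]))
        cat(sprintf("  %-24s rho=%+.3f p=%.4g n=%d\n", key,
                    x$validation[[key]]$rho, x$validation[[key]]$p,
                    x$validation[[key]]$n))
  }
  if (!is.null(x$specificity)) {
    cat("specificity (secondary behavior):\n")
    for (key in names(x$specificity))
      if (!is.null(x$specificity[[key]]))
        cat(sprintf("  %-24s rho=%+.3f p=%.4g n=%d\n", key,
                    x$specificity[[key]]$rho, x$specificity[[key]]$p,
                    x$specificity[[key]]$n))
  }
  invisible(x)
}
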