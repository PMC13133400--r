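#' External validation of a finalized CPM
#'
#' Applies a frozen model (consensus mask + refit coefficients, see
#' [finalize_model()]) to an external cohort — e.g. second-timepoint
#' connectomes for test-retest reliability — and correlates the predictions
#' with the external behavior. The external behavior never touches fitting:
#' predictions are a deterministic function of the model and the external
#' connectomes alone.
#'
#' @param fit a [cpm()] fit with non-empty consensus.
#' @param external an external [cpm_cohort()] with the fit's modalities.
#' @param behavior `"primary"` (the cohort's behavior column, default) or
#'   `"secondary"` (see [specificity_test()]).
#' @param method evaluation correlation (defaults to the fit's).
#' @return Object of class `cpm_validation`: `rho`, `p` (parametric
#'   t-approximation), `n`, `predictions` data frame, `behavior` label.
#' @export
external_validate <- function(fit, external,
                              behavior = c("primary", "secondary"),
                              method = fit$eval) {
  behavior <- match.arg(behavior)
  stopifnot(inherits(external, "cpm_cohort"))
  obs <- if (behavior == "primary") external$behavior else external$secondary
  if (is.null(obs))
    stop("external cohort has no secondary behavior")
  keep <- which(is.finite(obs))
  if (length(keep) < 3L)
    stop("fewer than 3 external subjects with the requested behavior")
  sub <- external[keep]
  pred <- predict(fit, newdata = sub)
  rho <- eval_cor(pred, obs[keep], method)
  structure(list(rho = rho,
                 p = eval_cor_p(pred, obs[keep], method),
                 n = length(keep), behavior = behavior, method = method,
                 predictions = data.frame(subject_id = sub$subjects,
                                          observed = obs[keep],
                                          predicted = unname(pred),
                                          stringsAsFactors = FALSE)),
            class = "cpm_validation")
}

#' @export
print.cpm_validation <- function(x, ...) {
  cat(sprintf("External validation (%s behavior): rho = %.3f, p = %.4g, n = %d\n",
              x$behavior, x$rho, x$p, x$n))
  invisible(x)
}

#' Behavioral specificity test
#'
#' Predicts a *different* behavior (the secondary score, e.g. rate of
#' torque development as a strength measure) from the balance-trained
#' consensus model. A specific model should show no systematic association
#' here; interpretation is left to the caller.
#'
#' @param fit a [cpm()] fit.
#' @param cohort a [cpm_cohort()] whose `secondary` field is present for at
#'   least 10 subjects.
#' @return A `cpm_validation` object (observed = secondary behavior).
#' @export
specificity_test <- function(fit, cohort) {
  if (is.null(cohort$secondary) || sum(is.finite(cohort$secondary)) < 10L)
    stop("secondary behavior required for at least 10 subjects")
  external_validate(fit, cohort, behavior = "secondary")
}
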