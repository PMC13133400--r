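# LOOCV machinery. Feature selection is recomputed inside every fold, so the
# left-out subject never influences their own edge mask (no leakage). The
# rank/residualization of the edge matrix within each fold does not depend on
# the behavior vector, so it is precomputed once per fold and reused across
# behavior vectors -- this is what makes permutation tests (B re-runs of the
# full LOOCV) affordable.

cpm_folds <- function(cohort, modalities, covariates) {
  n <- n_subjects(cohort)
  Z <- if (length(covariates))
    as.matrix(cohort$covariates[, covariates, drop = FALSE]) else NULL
  k <- if (is.null(Z)) 0L else ncol(Z)
  df <- n - 1L - 2L - k
  if (df < 1L) stop("too few subjects for LOOCV with these covariates")
  lapply(seq_len(n), function(f) {
    tr <- setdiff(seq_len(n), f)
    Ztr <- if (is.null(Z)) NULL else Z[tr, , drop = FALSE]
    Q <- rank_design_q(Ztr, n - 1L)
    Xres <- lapply(modalities, function(mod)
      residualize_unit(col_ranks(cohort$edges[[mod]][tr, , drop = FALSE]), Q))
    names(Xres) <- modalities
    list(test = f, train = tr, Q = Q, Xres = Xres, df = df)
  })
}

# per-fold edgewise rho and p for each column of the behavior matrix Y
fold_assoc <- function(fold, Y) {
  Ytr <- Y[fold$train, , drop = FALSE]
  Yres <- residualize_unit(col_ranks(Ytr), fold$Q)
  lapply(fold$Xres, function(Xr) {
    RHO <- crossprod(Xr, Yres)            # n_edges x B
    RHO[!is.finite(RHO)] <- 0
    RHO <- pmin(pmax(RHO, -1), 1)
    list(rho = RHO, p = rho_to_p(RHO, fold$df))
  })
}

mask_from_rp <- function(rho, p, threshold, sign) {
  which(p < threshold & (if (sign == "positive") rho > 0 else rho < 0))
}

# fit intercept + one slope per (non-degenerate) summary predictor and
# predict the left-out subject; minimum-norm fallback on rank deficiency
fold_fit_predict <- function(S_tr, y_tr, s_test) {
  keep <- apply(S_tr, 2L, stats::sd) > 0
  D <- cbind(1, S_tr[, keep, drop = FALSE])
  collinear <- FALSE
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    collinear <- TRUE
    sv <- svd(D)
    pos <- sv$d > max(sv$d) * 1e-10
    beta <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], y_tr)) / sv$d[pos])
  } else beta <- qr.coef(qd, y_tr)
  pred <- sum(c(1, s_test[keep]) * beta)
  list(pred = pred, collinear = collinear)
}

# run the LOOCV prediction step for every column of Y at one threshold.
# Returns predictions (n x B), per-column empty-fold counts, collinearity
# flag, and (for B = 1) the per-fold masks.
loocv_core <- function(cohort, folds, modalities, Y, threshold, sign,
                       keep_masks = FALSE) {
  n <- n_subjects(cohort)
  B <- ncol(Y)
  preds <- matrix(NA_real_, n, B)
  empty <- integer(B)
  collinear <- FALSE
  mask_sizes <- 0
  masks <- if (keep_masks) vector("list", n)
  for (f in seq_len(n)) {
    fold <- folds[[f]]
    assoc <- fold_assoc(fold, Y)
    for (b in seq_len(B)) {
      mk <- lapply(modalities, function(mod)
        mask_from_rp(assoc[[mod]]$rho[, b], assoc[[mod]]$p[, b],
                     threshold, sign))
      names(mk) <- modalities
      mask_sizes <- mask_sizes + sum(lengths(mk)) / (n * B)
      y_tr <- Y[fold$train, b]
      if (all(lengths(mk) == 0L)) {
        empty[b] <- empty[b] + 1L
        preds[f, b] <- mean(y_tr)
      } else {
        S_tr <- vapply(modalities, function(mod)
          summary_score(cohort$edges[[mod]][fold$train, , drop = FALSE],
                        mk[[mod]]), numeric(n - 1L))
        s_test <- vapply(modalities, function(mod)
          summary_score(cohort$edges[[mod]][fold$test, ], mk[[mod]]),
          numeric(1L))
        fit <- fold_fit_predict(S_tr, y_tr, s_test)
        preds[f, b] <- fit$pred
        collinear <- collinear || fit$collinear
      }
      if (keep_masks && b == 1L) masks[[f]] <- mk
    }
  }
  list(preds = preds, empty = empty, collinear = collinear,
       masks = masks, mean_mask_size = mask_sizes)
}

eval_cor <- function(pred, obs, method) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(0)
  stats::cor(pred, obs, method = method)
}

eval_cor_p <- function(pred, obs, method) {
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0) return(1)
  stats::cor.test(pred, obs, method = method, exact = FALSE)$p.value
}

#' Stability-aware threshold selection rule
#'
#' Given the evaluation correlation at every grid threshold, a threshold is
#' *eligible* when the variance of the correlation over its centered window
#' of `window` grid neighbors is at or below the `quantile` quantile of all
#' window variances; among eligible thresholds the one with the highest
#' correlation wins, ties broken toward the smaller threshold. If no
#' threshold is eligible the global maximum is returned with a warning.
#'
#' @param grid numeric vector of thresholds (ascending).
#' @param rho evaluation correlation at each grid threshold.
#' @param window odd window width in grid steps (default 5).
#' @param quantile stability quantile in (0, 1] (default 0.5, the median).
#' @return List: `threshold`, `table` (threshold, rho, window variance,
#'   eligibility).
#' @export
select_stable_threshold <- function(grid, rho, window = 5L, quantile = 0.5) {
  stopifnot(length(grid) == length(rho), window >= 1L, window %% 2L == 1L)
  T <- length(grid)
  h <- (window - 1L) %/% 2L
  wv <- vapply(seq_len(T), function(i) {
    w <- max(1L, i - h):min(T, i + h)
    if (length(w) > 1L) stats::var(rho[w]) else 0
  }, numeric(1L))
  eligible <- wv <= stats::quantile(wv, quantile, na.rm = TRUE, names = FALSE)
  eligible[is.na(eligible)] <- FALSE
  tab <- data.frame(threshold = grid, rho = rho, window_var = wv,
                    eligible = eligible)
  cand <- which(eligible)
  if (!length(cand)) {
    warning("stability criterion unsatisfiable; falling back to global maximum")
    cand <- seq_len(T)
  }
  best <- cand[which.max(rho[cand])]  # which.max -> first, i.e. smallest threshold
  list(threshold = grid[best], table = tab)
}

#' Threshold search over the p-value grid
#'
#' Runs the full LOOCV at every grid threshold and applies
#' [select_stable_threshold()]: the selected threshold maximizes the
#' cross-validated prediction correlation subject to local stability of the
#' correlation across neighboring thresholds. The default grid spans
#' 0.0001 to 0.05 in steps of 0.0001.
#'
#' @param cohort a [cpm_cohort()].
#' @param modality modality (or modalities, for the combined model).
#' @param sign `"positive"` or `"negative"` network.
#' @param covariates covariate column names (default age and sex).
#' @param grid threshold grid.
#' @param window,quantile stability parameters, see
#'   [select_stable_threshold()].
#' @param eval evaluation correlation, `"spearman"` (default) or
#'   `"pearson"`.
#' @return List: `threshold`, `table` (threshold, rho, window variance,
#'   eligibility, mean mask size).
#' @export
optimize_threshold <- function(cohort, modality = "functional",
                               sign = c("negative", "positive"),
                               covariates = c("age", "sex"),
                               grid = seq(1e-4, 0.05, by = 1e-4),
                               window = 5L, quantile = 0.5,
                               eval = c("spearman", "pearson")) {
  sign <- match.arg(sign)
  eval <- match.arg(eval)
  covariates <- intersect(covariates, names(cohort$covariates))
  folds <- cpm_folds(cohort, modality, covariates)
  n <- n_subjects(cohort)
  y <- cohort$behavior
  Y <- matrix(y, ncol = 1L)
  # per-fold association is threshold-free: compute once, reuse per threshold
  assoc <- lapply(folds, fold_assoc, Y = Y)
  rho_t <- numeric(length(grid))
  msize <- numeric(length(grid))
  for (ti in seq_along(grid)) {
    preds <- numeric(n)
    for (f in seq_len(n)) {
      mk <- lapply(modality, function(mod)
        mask_from_rp(assoc[[f]][[mod]]$rho[, 1L], assoc[[f]][[mod]]$p[, 1L],
                     grid[ti], sign))
      names(mk) <- modality
      msize[ti] <- msize[ti] + sum(lengths(mk)) / n
      y_tr <- y[folds[[f]]$train]
      if (all(lengths(mk) == 0L)) {
        preds[f] <- mean(y_tr)
      } else {
        S_tr <- vapply(modality, function(mod)
          summary_score(cohort$edges[[mod]][folds[[f]]$train, , drop = FALSE],
                        mk[[mod]]), numeric(n - 1L))
        s_test <- vapply(modality, function(mod)
          summary_score(cohort$edges[[mod]][folds[[f]]$test, ], mk[[mod]]),
          numeric(1L))
        preds[f] <- fold_fit_predict(S_tr, y_tr, s_test)$pred
      }
    }
    rho_t[ti] <- eval_cor(preds, y, eval)
  }
  sel <- select_stable_threshold(grid, rho_t, window, quantile)
  sel$table$mean_mask_size <- msize
  sel
}

#' Fit a connectome-based predictive model
#'
#' The main fitting function. For each leave-one-out fold it (i) computes
#' edgewise partial Spearman correlations between edge weight and behavior
#' on the training subjects (covariates partialled out), (ii) keeps the
#' edges with `p < threshold` of the requested sign, (iii) sums each
#' training subject's selected edge weights into a summary score per
#' modality, (iv) fits a linear regression of behavior on the summary
#' score(s), and (v) predicts the left-out subject from their own summary.
#' Model quality is the correlation between the pooled cross-validated
#' predictions and the observed scores. Edges surviving every fold form the
#' consensus connectome, on which final coefficients are refit using all
#' subjects (see [finalize_model()]).
#'
#' With two modalities, feature selection runs independently per modality at
#' the shared threshold and both summary scores enter one two-slope
#' regression (the combined model).
#'
#' @param cohort a [cpm_cohort()].
#' @param modality `"functional"`, `"structural"`, or both for the
#'   combined model.
#' @param sign `"negative"` (edges inversely related to sway area, i.e.
#'   positively related to balance ability) or `"positive"`.
#' @param threshold fixed p-value cutoff, or `NULL` to search the grid via
#'   [optimize_threshold()].
#' @param covariates covariate column names to partial out (default age and
#'   sex; add e.g. `"mean_fd"` for motion control).
#' @param eval evaluation correlation (`"spearman"` default).
#' @param grid,window,quantile threshold-search settings, used when
#'   `threshold` is `NULL`.
#' @return An object of class `cpm`. Key components: `predictions` (data
#'   frame of observed and cross-validated predicted scores), `rho` and
#'   `p_parametric` (evaluation correlation and its t-approximation
#'   p-value), `threshold`, `fold_masks`, `consensus` (per-modality edge
#'   positions present in all folds), `coefficients` (consensus refit),
#'   `threshold_table` when searched.
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 20, n_nodes = 20,
#'                                    n_planted = 10, seed = 7))
#' fit <- cpm(sim$tp1, threshold = 0.05)
#' fit$rho
#' @seealso [permutation_test()], [external_validate()],
#'   [consensus_edges()], [summary.cpm()]
#' @export
cpm <- function(cohort, modality = "functional",
                sign = c("negative", "positive"), threshold = NULL,
                covariates = c("age", "sex"),
                eval = c("spearman", "pearson"),
                grid = seq(1e-4, 0.05, by = 1e-4),
                window = 5L, quantile = 0.5) {
  sign <- match.arg(sign)
  eval <- match.arg(eval)
  stopifnot(inherits(cohort, "cpm_cohort"))
  modality <- match.arg(modality, c("functional", "structural"),
                        several.ok = TRUE)
  miss <- setdiff(modality, names(cohort$edges))
  if (length(miss))
    stop("cohort lacks requested modality: ", paste(miss, collapse = ", "))
  covariates <- intersect(covariates, names(cohort$covariates))
  n <- n_subjects(cohort)
  if (n < 5L) stop("LOOCV requires at least 5 subjects")

  threshold_table <- NULL
  if (is.null(threshold)) {
    sel <- optimize_threshold(cohort, modality, sign, covariates, grid,
                              window, quantile, eval)
    threshold <- sel$threshold
    threshold_table <- sel$table
  }
  folds <- cpm_folds(cohort, modality, covariates)
  y <- cohort$behavior
  run <- loocv_core(cohort, folds, modality, matrix(y, ncol = 1L),
                    threshold, sign, keep_masks = TRUE)
  if (run$empty[1L] == n)
    stop("no predictive edges at this threshold (all folds empty)")
  if (run$empty[1L] > 0L)
    warning(sprintf("%d of %d folds had an empty edge mask; training-mean prediction used",
                    run$empty[1L], n))
  if (run$collinear)
    warning("collinear summary predictors; minimum-norm least squares used")
  preds <- run$preds[, 1L]
  fit <- structure(list(
    call = match.call(), modalities = modality, sign = sign,
    threshold = threshold, threshold_table = threshold_table,
    covariates = covariates, eval = eval,
    n = n, subjects = cohort$subjects, atlas = cohort$atlas,
    predictions = data.frame(subject_id = cohort$subjects, observed = y,
                             predicted = preds, stringsAsFactors = FALSE),
    rho = eval_cor(preds, y, eval),
    p_parametric = eval_cor_p(preds, y, eval),
    fold_masks = run$masks, empty_folds = run$empty[1L],
    collinear = run$collinear), class = "cpm")
  fin <- tryCatch(finalize_model(cohort, run$masks, modality),
                  error = function(e) {
                    warning(conditionMessage(e))
                    list(consensus = lapply(stats::setNames(modality, modality),
                                            function(m) integer()),
                         coefficients = NULL)
                  })
  fit$consensus <- fin$consensus
  fit$coefficients <- fin$coefficients
  fit
}

#' Finalize a CPM for external use
#'
#' Intersects the per-fold edge masks into the consensus connectome and
#' refits the linear coefficients on *all* subjects using consensus-mask
#' summary scores. These frozen quantities are what travels to external
#' (e.g. second-timepoint) data.
#'
#' @param cohort the training [cpm_cohort()].
#' @param fold_masks per-fold named lists of edge positions (from [cpm()]).
#' @param modalities modalities to include.
#' @return List: `consensus` (per-modality edge positions), `coefficients`
#'   (named: `(Intercept)` then one slope per modality).
#' @export
finalize_model <- function(cohort, fold_masks,
                           modalities = names(fold_masks[[1L]])) {
  consensus <- lapply(stats::setNames(modalities, modalities), function(mod)
    Reduce(intersect, lapply(fold_masks, `[[`, mod)))
  if (all(lengths(consensus) == 0L))
    stop("no consensus edges; external validation impossible")
  S <- vapply(modalities, function(mod)
    summary_score(cohort$edges[[mod]], consensus[[mod]]),
    numeric(n_subjects(cohort)))
  keep <- apply(S, 2L, stats::sd) > 0
  D <- cbind(1, S[, keep, drop = FALSE])
  beta_all <- numeric(length(modalities) + 1L)
  beta_all[c(TRUE, keep)] <- qr.coef(qr(D), cohort$behavior)
  names(beta_all) <- c("(Intercept)", modalities)
  list(consensus = consensus, coefficients = beta_all)
}

#' @export
print.cpm <- function(x, ...) {
  cat(sprintf("CPM fit: %s network, modality %s\n", x$sign,
              paste(x$modalities, collapse = "+")))
  cat(sprintf("  n = %d subjects, p-threshold = %.4g%s\n", x$n, x$threshold,
              if (!is.null(x$threshold_table)) " (searched)" else ""))
  cat(sprintf("  LOOCV %s rho = %.3f (parametric p = %.4g)\n", x$eval,
              x$rho, x$p_parametric))
  cs <- vapply(x$consensus, length, integer(1L))
  cat(sprintf("  consensus edges: %s\n",
              paste(sprintf("%s %d", names(cs), cs), collapse = ", ")))
  invisible(x)
}

#' Summarize a CPM fit
#'
#' Attaches consensus-connectome structure to the fit: network distribution
#' and the highest-degree nodes, per modality.
#'
#' @param object a `cpm` fit.
#' @param top_k how many top-degree nodes to report (default 20).
#' @param convention network counting convention, see
#'   [network_distribution()].
#' @param ... unused.
#' @return An object of class `summary.cpm`.
#' @export
summary.cpm <- function(object, top_k = 20L,
                        convention = c("endpoint", "within_double"), ...) {
  convention <- match.arg(convention)
  nets <- lapply(object$consensus, function(e)
    if (length(e)) network_distribution(e, object$atlas,
                                        convention = convention))
  degs <- lapply(object$consensus, function(e)
    if (length(e)) node_degree_table(e, object$atlas, top_k = top_k))
  structure(list(fit = object, networks = nets, degrees = degs),
            class = "summary.cpm")
}

#' @export
print.summary.cpm <- function(x, ...) {
  print(x$fit)
  for (mod in names(x$networks)) {
    if (is.null(x$networks[[mod]])) next
    cat(sprintf("\n%s consensus network shares:\n", mod))
    pr <- x$networks[[mod]]$proportions
    pr <- sort(pr[pr > 0], decreasing = TRUE)
    for (nm in names(pr)) cat(sprintf("  %-20s %5.1f%%\n", nm, 100 * pr[nm]))
    cat(sprintf("top nodes by degree (%s):\n", mod))
    print(utils::head(x$degrees[[mod]], 5L), row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cpm <- function(object, ...) object$coefficients

#' @export
fitted.cpm <- function(object, ...)
  stats::setNames(object$predictions$predicted, object$predictions$subject_id)

#' @export
residuals.cpm <- function(object, ...)
  stats::setNames(object$predictions$observed - object$predictions$predicted,
                  object$predictions$subject_id)

#' Predict behavior for new subjects from a finalized CPM
#'
#' Applies the frozen consensus mask and frozen coefficients to a new
#' cohort's connectomes. Without `newdata` the cross-validated LOOCV
#' predictions are returned.
#'
#' @param object a `cpm` fit with non-empty consensus.
#' @param newdata a [cpm_cohort()] providing the fit's modalities.
#' @param ... unused.
#' @return Named numeric vector of predicted behavior scores.
#' @export
predict.cpm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  stopifnot(inherits(newdata, "cpm_cohort"))
  if (is.null(object$coefficients))
    stop("model has no consensus coefficients; cannot predict new data")
  miss <- setdiff(object$modalities, names(newdata$edges))
  if (length(miss))
    stop("newdata lacks modality: ", paste(miss, collapse = ", "))
  S <- vapply(object$modalities, function(mod)
    summary_score(newdata$edges[[mod]], object$consensus[[mod]]),
    numeric(n_subjects(newdata)))
  pred <- drop(cbind(1, S) %*% object$coefficients)
  stats::setNames(pred, newdata$subjects)
}

#' Plot a CPM fit
#'
#' Predicted versus observed sway area (left) and, when a threshold search
#' was run, the prediction-correlation-versus-threshold curve (right).
#'
#' @param x a `cpm` fit.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.cpm <- function(x, ...) {
  two <- !is.null(x$threshold_table)
  if (two) {
    old <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(old))
  }
  graphics::plot(x$predictions$predicted, x$predictions$observed,
                 xlab = "predicted sway area (cm^2)",
                 ylab = "observed sway area (cm^2)",
                 main = sprintf("%s %s network: rho = %.2f",
                                paste(x$modalities, collapse = "+"),
                                x$sign, x$rho), ...)
  graphics::abline(stats::lm(observed ~ predicted, data = x$predictions),
                   lty = 2)
  if (two) {
    tt <- x$threshold_table
    graphics::plot(tt$threshold, tt$rho, type = "l",
                   xlab = "p-value threshold", ylab = "LOOCV rho",
                   main = "threshold search")
    graphics::abline(v = x$threshold, lty = 3)
  }
  invisible(x)
}
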