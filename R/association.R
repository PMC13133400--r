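# Edgewise partial Spearman association: the CPM feature-selection statistic.
#
# Mechanics (rank-based partial correlation): rank-transform every edge
# column, the behavior and every covariate (average ranks on ties);
# residualize the ranked edge and ranked behavior on [1, ranked covariates]
# by least squares; the statistic is the Pearson correlation of the two
# residual vectors. p-values come from the t approximation with
# df = n - 2 - n_covariates.

col_ranks <- function(x) apply(as.matrix(x), 2L, rank)

# orthonormal basis of the covariate design (intercept + ranked covariates)
rank_design_q <- function(Z, n) {
  D <- cbind(rep(1, n), if (!is.null(Z) && NCOL(Z)) col_ranks(Z))
  qr.Q(qr(D))
}

# residualize columns of X against the column space of Q and scale each
# column to unit norm (zero-variance columns flagged NA)
residualize_unit <- function(X, Q) {
  R <- X - Q %*% crossprod(Q, X)
  nrm <- sqrt(colSums(R^2))
  nrm[nrm < 1e-12] <- NA_real_
  sweep(R, 2L, nrm, `/`)
}

rho_to_p <- function(rho, df) {
  r2 <- pmin(rho^2, 1 - 1e-15)
  tval <- abs(rho) * sqrt(df / (1 - r2))
  2 * stats::pt(tval, df, lower.tail = FALSE)
}

#' Edgewise partial Spearman correlation with behavior
#'
#' For every edge, the partial Spearman correlation between edge weight and
#' the behavior score, controlling for covariates: all variables are
#' rank-transformed (average ranks on ties), ranked edge and ranked behavior
#' are residualized on the ranked covariates by least squares, and the
#' statistic is the Pearson correlation of the residuals. Two-sided p-values
#' use the t approximation with `df = n - 2 - n_covariates`.
#'
#' @param X `n_subjects x n_edges` edge-weight matrix.
#' @param behavior numeric behavior vector (must not be constant).
#' @param covariates optional numeric matrix/data frame of covariates;
#'   constant columns are dropped with a warning.
#' @return List of class `edge_association`: `rho`, `p` (per edge), `df`,
#'   `n`, `n_covariates`. Edges with zero variance get `rho = 0`, `p = 1`.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(30 * 10), 30)
#' a <- edge_behavior_association(X, X[, 1] + rnorm(30, sd = 0.2))
#' which.min(a$p)
#' @export
edge_behavior_association <- function(X, behavior, covariates = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("at least 4 subjects required")
  behavior <- as.numeric(behavior)
  if (length(behavior) != n) stop("behavior length must match subjects")
  if (stats::sd(behavior) == 0) stop("behavior is constant")
  Z <- NULL
  if (!is.null(covariates) && NCOL(covariates)) {
    Z <- as.matrix(as.data.frame(covariates))
    keep <- apply(Z, 2L, stats::sd) > 0
    if (!all(keep)) {
      warning("dropping constant covariate(s): ",
              paste(colnames(Z)[!keep], collapse = ", "))
      Z <- Z[, keep, drop = FALSE]
    }
    if (!ncol(Z)) Z <- NULL
  }
  k <- if (is.null(Z)) 0L else ncol(Z)
  df <- n - 2L - k
  if (df < 1L) stop("too few subjects for the covariate count (df < 1)")
  Q <- rank_design_q(Z, n)
  Xres <- residualize_unit(col_ranks(X), Q)
  yres <- residualize_unit(matrix(rank(behavior), ncol = 1L), Q)
  rho <- as.numeric(crossprod(Xres, yres))
  dead <- !is.finite(rho)
  rho[dead] <- 0
  rho <- pmin(pmax(rho, -1), 1)
  p <- rho_to_p(rho, df)
  p[dead] <- 1
  structure(list(rho = rho, p = p, df = df, n = n, n_covariates = k),
            class = "edge_association")
}

#' Threshold edgewise associations into a signed edge mask
#'
#' Selects the edges with `p < threshold` whose correlation sign matches the
#' requested network: the positive network holds edges positively correlated
#' with the behavior metric (sway area), the negative network those
#' negatively correlated (hence positively related to balance ability).
#'
#' @param assoc an [edge_behavior_association()] result.
#' @param threshold p-value cutoff in (0, 1].
#' @param sign `"positive"` or `"negative"`.
#' @return Integer vector of selected edge positions (1-based column
#'   indices); empty masks are allowed (a warning is attached upstream where
#'   it matters).
#' @export
select_edges <- function(assoc, threshold, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]")
  keep <- assoc$p < threshold &
    (if (sign == "positive") assoc$rho > 0 else assoc$rho < 0)
  which(keep)
}

#' Single-subject network summary score
#'
#' The per-subject predictor of CPM: the sum of the subject's edge weights
#' over a selected edge mask. An empty mask gives 0.
#'
#' @param edges a subject's edge-weight vector, or an
#'   `n_subjects x n_edges` matrix (then a vector of scores is returned).
#' @param mask integer edge positions from [select_edges()].
#' @return Summed weight(s).
#' @export
summary_score <- function(edges, mask) {
  n_edges <- if (is.matrix(edges)) ncol(edges) else length(edges)
  if (length(mask) && (min(mask) < 1L || max(mask) > n_edges))
    stop("mask edge positions out of bounds")
  if (is.matrix(edges)) {
    if (!length(mask)) return(numeric(nrow(edges)))
    rowSums(edges[, mask, drop = FALSE])
  } else {
    if (!length(mask)) return(0)
    sum(edges[mask])
  }
}
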