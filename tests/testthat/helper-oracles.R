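# Independent reference implementations used to cross-check the package.

# edge-by-edge partial Spearman: ranks, lm residualization, cor.test-style t
oracle_partial_spearman <- function(X, y, Z = NULL) {
  n <- nrow(X)
  k <- if (is.null(Z)) 0L else ncol(as.matrix(Z))
  ry <- rank(y)
  D <- if (is.null(Z)) matrix(1, n, 1) else cbind(1, apply(as.matrix(Z), 2, rank))
  ey <- stats::lm.fit(D, ry)$residuals
  df <- n - 2L - k
  out <- t(vapply(seq_len(ncol(X)), function(e) {
    ex <- stats::lm.fit(D, rank(X[, e]))$residuals
    if (stats::sd(ex) == 0) return(c(0, 1))
    r <- stats::cor(ex, ey)
    tv <- abs(r) * sqrt(df / (1 - min(r^2, 1 - 1e-15)))
    c(r, 2 * stats::pt(tv, df, lower.tail = FALSE))
  }, numeric(2L)))
  list(rho = out[, 1L], p = out[, 2L], df = df)
}

# brute-force Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    adj[i] <- min(1, min(m / js * p[o[js]]))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# small hand-built cohort: deterministic random edges, optional planted signal
make_tiny_cohort <- function(n = 20L, n_nodes = 12L, seed = 1L,
                             planted = integer(), effect = 0,
                             modalities = "functional") {
  set.seed(seed)
  E <- n_nodes * (n_nodes - 1L) / 2L
  z <- rnorm(n)
  edges <- lapply(stats::setNames(modalities, modalities), function(m) {
    X <- matrix(rnorm(n * E), n, E)
    for (e in planted) X[, e] <- effect * z + sqrt(1 - effect^2) * rnorm(n)
    X
  })
  atlas <- cpm_atlas(rep_len(canonical_networks(), n_nodes))
  cpm_cohort(edges, behavior = 20 * exp(0.5 * (-z + rnorm(n, sd = 0.3))),
             atlas = atlas,
             covariates = data.frame(age = rnorm(n, 71, 5),
                                     sex = rbinom(n, 1, 0.5)))
}
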