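#' Specification for a synthetic connectome cohort
#'
#' Parameters of the generative model behind [simulate_cohort()]. Defaults
#' emulate the study design the package targets: 54 older-adult subjects,
#' two timepoints about three months apart with 48 subjects retested, a
#' strength measure available for 42, age and sex covariates, and a planted
#' subset of edges whose weights track the latent balance trait. The
#' default geometry uses 60 nodes (1770 edges) so full-pipeline runs stay
#' fast; `preset = "paper_scale"` switches to the 268-node atlas size.
#'
#' @param n_subjects subjects at timepoint 1 (default 54).
#' @param n_nodes atlas nodes (default 60).
#' @param n_planted edges carrying a true behavior effect (default 40).
#' @param effect_size target magnitude of the planted edge-trait
#'   correlation, in (0, 1) (default 0.5).
#' @param covariate_effect weight of the combined standardized age/sex
#'   covariate on behavior and (via random per-edge loadings) on edges
#'   (default 0.3).
#' @param sc_fc_coupling probability that a planted structural edge shares
#'   its effect sign with its functional counterpart (default 0.8).
#' @param retest_reliability cross-timepoint correlation of edges and of
#'   the behavior latent, in \[0, 1) (default 0.7).
#' @param behavior_noise sd of the behavior latent noise (default 0.2).
#' @param n_tp2 subjects retested at timepoint 2 (default 48).
#' @param n_secondary subjects with the secondary (strength) behavior
#'   (default 42).
#' @param seed mandatory RNG seed.
#' @param preset `"default"` or `"paper_scale"` (268 nodes).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 54L, n_nodes = 60L, n_planted = 40L,
                        effect_size = 0.5, covariate_effect = 0.3,
                        sc_fc_coupling = 0.8, retest_reliability = 0.7,
                        behavior_noise = 0.2, n_tp2 = 48L,
                        n_secondary = 42L, seed,
                        preset = c("default", "paper_scale")) {
  preset <- match.arg(preset)
  if (preset == "paper_scale") n_nodes <- 268L
  if (missing(seed)) stop("a seed is mandatory")
  n_edges <- n_nodes * (n_nodes - 1L) / 2L
  if (n_planted > n_edges) stop("more planted edges than edges exist")
  for (v in c(effect_size, sc_fc_coupling, retest_reliability))
    if (v < 0 || v >= 1) stop("correlation parameters must lie in [0, 1)")
  n_tp2 <- min(n_tp2, n_subjects)
  n_secondary <- min(n_secondary, n_subjects)
  structure(as.list(environment())[c(
    "n_subjects", "n_nodes", "n_planted", "effect_size", "covariate_effect",
    "sc_fc_coupling", "retest_reliability", "behavior_noise", "n_tp2",
    "n_secondary", "seed")], class = "cohort_spec")
}

#' Simulate a two-timepoint connectome cohort
#'
#' Generative model: each subject carries a latent balance trait
#' `z ~ N(0,1)`. The behavior latent is
#' `lin = -z + covariate_effect * c + noise` with `c` the combined
#' standardized age/sex covariate, and the recorded sway area is the
#' positively skewed strictly increasing transform `20 * exp(0.5 * lin)`
#' (cm^2) — larger trait, smaller sway area, so planted edges with a
#' positive trait loading belong to the *negative* network. Planted
#' functional edges follow `beta * s_e * z + sqrt(1-beta^2) * noise` on the
#' Fisher-z scale (signs `s_e` half positive, half negative, so both
#' network signs are exercised) plus a fixed per-edge baseline and a random
#' covariate loading; non-planted edges are baseline plus noise. Structural
#' edges use the same planted positions with signs shared at probability
#' `sc_fc_coupling` and an exponential link, giving non-negative
#' heavy-tailed weights. Timepoint 2 is a correlated redraw:
#' `x2 = r * x1 + sqrt(1-r^2) * fresh` on each latent scale, at
#' `r = retest_reliability`, for the first `n_tp2` subjects. The secondary
#' behavior (strength; N·m/s scale) is drawn independently of `z`.
#'
#' @param spec a [cohort_spec()].
#' @return List: `tp1` and `tp2` ([cpm_cohort()] objects with functional
#'   and structural modalities) and `truth` (planted edge positions, signs
#'   per modality, and the spec).
#' @examples
#' sim <- simulate_cohort(cohort_spec(n_subjects = 20, n_nodes = 16,
#'                                    n_planted = 8, seed = 1))
#' sim$tp1
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rng <- local_rng(spec$seed)
  on.exit(restore_rng(rng))
  n <- spec$n_subjects
  E <- spec$n_nodes * (spec$n_nodes - 1L) / 2L
  beta <- spec$effect_size

  age <- stats::rnorm(n, 71.1, 4.8)
  sex <- stats::rbinom(n, 1L, 0.5)
  cc <- (scale_safe(age) + scale_safe(sex)) / sqrt(2)
  z <- stats::rnorm(n)
  lin1 <- -z + spec$covariate_effect * cc +
    stats::rnorm(n, sd = spec$behavior_noise)

  planted <- sort(sample.int(E, spec$n_planted))
  s_fc <- rep_len(c(1, -1), spec$n_planted)
  flip <- stats::runif(spec$n_planted) >= spec$sc_fc_coupling
  s_sc <- ifelse(flip, -s_fc, s_fc)

  base_fc <- stats::rnorm(E, 0, 0.2)
  base_sc <- stats::rnorm(E, 0, 0.3)
  gamma <- stats::rnorm(E, 0, spec$covariate_effect / 4)  # covariate confound

  load_fc <- numeric(E); load_fc[planted] <- beta * s_fc
  load_sc <- numeric(E); load_sc[planted] <- beta * s_sc
  resid_sd <- function(load) sqrt(pmax(1 - load^2, 1e-6))

  draw_latent <- function(load) {
    noise <- matrix(stats::rnorm(n * E), n, E)
    sweep(noise, 2L, resid_sd(load), `*`) + outer(z, load) +
      outer(as.numeric(cc), gamma)
  }
  fc1_lat <- draw_latent(load_fc)
  sc1_lat <- draw_latent(load_sc)

  # timepoint-2 correlated redraw on the latent scales
  r <- spec$retest_reliability
  redraw <- function(x1) {
    r * x1 + sqrt(1 - r^2) * matrix(stats::rnorm(n * E), n, E)
  }
  fc2_lat <- redraw(fc1_lat)
  sc2_lat <- redraw(sc1_lat)
  lin2 <- r * lin1 + sqrt(1 - r^2) * stats::rnorm(n, sd = stats::sd(lin1))

  to_fc <- function(lat) 0.3 * sweep(lat, 2L, base_fc, `+`)
  to_sc <- function(lat) exp(0.6 * sweep(lat, 2L, base_sc, `+`))
  behavior <- function(lin) 20 * exp(0.5 * lin)

  atlas <- cpm_atlas(rep_len(canonical_networks(), spec$n_nodes),
                     volumes = exp(stats::rnorm(spec$n_nodes,
                                                log(1500), 0.3)))
  w <- stats::rnorm(n)
  secondary <- 150 * exp(0.3 * w)
  secondary[seq_len(n) > spec$n_secondary] <- NA_real_

  ids <- sprintf("s%03d", seq_len(n))
  tp1 <- cpm_cohort(list(functional = to_fc(fc1_lat),
                         structural = to_sc(sc1_lat)),
                    behavior(lin1), atlas, subjects = ids,
                    covariates = data.frame(age = age, sex = sex),
                    secondary = secondary, timepoint = "tp1")
  k2 <- seq_len(spec$n_tp2)
  tp2 <- cpm_cohort(list(functional = to_fc(fc2_lat)[k2, , drop = FALSE],
                         structural = to_sc(sc2_lat)[k2, , drop = FALSE]),
                    behavior(lin2)[k2], atlas, subjects = ids[k2],
                    covariates = data.frame(age = age, sex = sex)[k2, ],
                    timepoint = "tp2")
  list(tp1 = tp1, tp2 = tp2,
       truth = list(planted = planted, sign_functional = s_fc,
                    sign_structural = s_sc, latent = z, spec = spec))
}

scale_safe <- function(x) {
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Simulate a center-of-pressure recording
#'
#' Draws i.i.d. bivariate normal COP samples with a requested covariance —
#' the substrate for sway-area computations.
#'
#' @param covariance symmetric positive semidefinite 2x2 matrix (cm^2).
#' @param n_samples number of samples.
#' @param sampling_rate sampling rate in Hz (default 4000, a 4 kHz force
#'   plate).
#' @param seed RNG seed.
#' @return A `cop_recording` (see [read_cop()]).
#' @export
simulate_cop <- function(covariance, n_samples, sampling_rate = 4000,
                         seed = 1L) {
  S <- as.matrix(covariance)
  if (!identical(dim(S), c(2L, 2L)) || max(abs(S - t(S))) > 1e-8)
    stop("covariance must be a symmetric 2x2 matrix")
  eg <- eigen(S, symmetric = TRUE)
  if (min(eg$values) < -1e-10 * max(abs(eg$values), 1))
    stop("covariance must be positive semidefinite")
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2L)
  xy <- matrix(stats::rnorm(2L * n_samples), ncol = 2L) %*% t(A)
  structure(list(xy = xy, sampling_rate = sampling_rate),
            class = "cop_recording")
}
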