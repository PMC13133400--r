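test_that("finalize refits consensus coefficients reproducibly", {
  coh <- make_tiny_cohort(n = 24L, n_nodes = 16L, seed = 41,
                          planted = 1:10, effect = 0.7)
  fit <- cpm(coh, "functional", "negative", threshold = 0.05)
  fin <- finalize_model(coh, fit$fold_masks, "functional")
  expect_equal(fin$consensus$functional, fit$consensus$functional)
  expect_equal(fin$coefficients, fit$coefficients)
  # refit is idempotent: ordinary least squares on consensus scores
  s <- summary_score(coh$edges$functional, fin$consensus$functional)
  ref <- stats::lm(coh$behavior ~ s)
  expect_equal(unname(fin$coefficients), unname(coef(ref)), tolerance = 1e-8)
  # perturbing one behavior value moves coefficients, not the mask
  coh2 <- coh; coh2$behavior[3] <- coh2$behavior[3] + 15
  fin2 <- finalize_model(coh2, fit$fold_masks, "functional")
  expect_equal(fin2$consensus, fin$consensus)
  expect_false(isTRUE(all.equal(fin2$coefficients, fin$coefficients)))
  expect_error(finalize_model(coh, lapply(fit$fold_masks, function(m)
    list(functional = integer())), "functional"), "no consensus")
})

test_that("external validation on the training set equals the in-sample refit", {
  coh <- make_tiny_cohort(n = 24L, n_nodes = 16L, seed = 43,
                          planted = 1:10, effect = 0.7)
  fit <- cpm(coh, "functional", "negative", threshold = 0.05)
  ev <- external_validate(fit, coh)
  pred <- predict(fit, newdata = coh)
  expect_equal(ev$rho, stats::cor(pred, coh$behavior, method = "spearman"))
  expect_equal(ev$n, 24L)
})

test_that("external predictions are frozen: shuffled behavior moves rho only", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 30, n_nodes = 20,
                                     n_planted = 12, seed = 6))
  fit <- cpm(sim$tp1, "functional", "negative", threshold = 0.05)
  ev1 <- external_validate(fit, sim$tp2)
  shuf <- sim$tp2
  set.seed(1); shuf$behavior <- sample(shuf$behavior)
  ev2 <- external_validate(fit, shuf)
  expect_equal(ev1$predictions$predicted, ev2$predictions$predicted)
  expect_false(isTRUE(all.equal(ev1$rho, ev2$rho)))
})

test_that("test-retest transfer strengthens with retest reliability", {
  rhos <- vapply(c(0.3, 0.6, 0.9), function(r) {
    mean(vapply(1:3, function(s) {
      sim <- simulate_cohort(cohort_spec(n_subjects = 40, n_nodes = 24,
                                         n_planted = 16,
                                         retest_reliability = r,
                                         seed = 100 + s))
      fit <- cpm(sim$tp1, "functional", "negative", threshold = 0.05)
      external_validate(fit, sim$tp2)$rho
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(rhos) > 0))
  expect_gt(rhos[3], 0.2)
})

test_that("the combined model uses both modalities and nests cleanly", {
  # signal split across modalities: half the planted edges in each
  set.seed(77)
  n <- 40L; n_nodes <- 20L
  E <- n_nodes * (n_nodes - 1L) / 2L
  z <- rnorm(n)
  mk <- function(planted) {
    X <- matrix(rnorm(n * E), n, E)
    for (e in planted) X[, e] <- 0.7 * z + sqrt(1 - 0.49) * rnorm(n)
    X
  }
  atlas <- cpm_atlas(rep_len(canonical_networks(), n_nodes))
  coh <- cpm_cohort(list(functional = mk(1:8), structural = abs(mk(9:16))),
                    behavior = 20 * exp(0.5 * (-z + rnorm(n, sd = 0.3))),
                    atlas = atlas,
                    covariates = data.frame(age = rnorm(n, 71, 5),
                                            sex = rbinom(n, 1, 0.5)))
  f_fun <- suppressWarnings(cpm(coh, "functional", "negative",
                                threshold = 0.01))
  f_str <- suppressWarnings(cpm(coh, "structural", "negative",
                                threshold = 0.01))
  f_both <- suppressWarnings(cpm(coh, c("functional", "structural"),
                                 "negative", threshold = 0.01))
  expect_length(f_both$coefficients, 3L)
  expect_gte(f_both$rho, max(f_fun$rho, f_str$rho) - 0.05)

  # constant structural edges: combined collapses to the functional fit
  coh0 <- coh
  coh0$edges$structural[] <- 0.5
  f_nested <- cpm(coh0, c("functional", "structural"), "negative",
                  threshold = 0.01)
  f_single <- cpm(coh0, "functional", "negative", threshold = 0.01)
  expect_equal(f_nested$predictions$predicted,
               f_single$predictions$predicted, tolerance = 1e-8)
})

test_that("identical modalities trigger the collinearity fallback", {
  coh <- make_tiny_cohort(n = 20L, n_nodes = 14L, seed = 55,
                          planted = 1:8, effect = 0.8,
                          modalities = c("functional", "structural"))
  coh$edges$structural <- coh$edges$functional
  expect_warning(
    fit <- cpm(coh, c("functional", "structural"), "negative",
               threshold = 0.05),
    "collinear")
  expect_true(all(is.finite(fit$predictions$predicted)))
})

test_that("specificity test scores the secondary behavior with frozen models", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 30, n_nodes = 20,
                                     n_planted = 12, n_secondary = 18,
                                     seed = 9))
  fit <- cpm(sim$tp1, "functional", "negative", threshold = 0.05)
  sp <- specificity_test(fit, sim$tp1)
  expect_equal(sp$n, 18L)   # only subjects with a secondary score count
  expect_equal(sp$behavior, "secondary")
  # reduction: secondary identical to primary reproduces self-validation
  twin <- sim$tp1
  twin$secondary <- twin$behavior
  sp2 <- specificity_test(fit, twin)
  ev <- external_validate(fit, sim$tp1)
  expect_equal(sp2$rho, ev$rho)
  none <- sim$tp1; none$secondary <- NULL
  expect_error(specificity_test(fit, none), "secondary")
})
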