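test_that("LOOCV returns one prediction per subject and recovers planted signal", {
  coh <- make_tiny_cohort(n = 40L, n_nodes = 46L, seed = 21,
                          planted = 1:30, effect = 0.7)
  fit <- cpm(coh, "functional", "negative", threshold = 0.01)
  expect_equal(nrow(fit$predictions), 40L)
  expect_equal(fit$predictions$subject_id, coh$subjects)
  expect_length(fit$fold_masks, 40L)
  expect_gt(fit$rho, 0.5)
  # consensus is contained in every fold mask
  for (f in seq_len(40L))
    expect_true(all(fit$consensus$functional %in%
                      fit$fold_masks[[f]]$functional))
})

test_that("the left-out subject never influences their own fold", {
  coh <- make_tiny_cohort(n = 24L, n_nodes = 16L, seed = 31,
                          planted = 1:10, effect = 0.7)
  fit <- cpm(coh, "functional", "negative", threshold = 0.05)
  i <- 7L
  coh2 <- coh
  coh2$behavior[i] <- coh2$behavior[i] * 3 + 40   # perturb only subject i
  fit2 <- cpm(coh2, "functional", "negative", threshold = 0.05)
  expect_identical(fit$fold_masks[[i]], fit2$fold_masks[[i]])
  expect_equal(fit$predictions$predicted[i], fit2$predictions$predicted[i])
})

test_that("fitting is deterministic", {
  coh <- make_tiny_cohort(n = 18L, n_nodes = 14L, seed = 5,
                          planted = 1:8, effect = 0.6)
  f1 <- cpm(coh, "functional", "negative", threshold = 0.05)
  f2 <- cpm(coh, "functional", "negative", threshold = 0.05)
  expect_equal(f1$predictions, f2$predictions)
  expect_identical(f1$fold_masks, f2$fold_masks)
  expect_equal(f1$coefficients, f2$coefficients)
})

test_that("negative-network slope sign matches the balance interpretation", {
  # negative-network summary scores fall as sway area rises, so the fitted
  # slope on the summary predictor must be negative
  coh <- make_tiny_cohort(n = 40L, n_nodes = 20L, seed = 13,
                          planted = 1:12, effect = 0.7)
  fit <- cpm(coh, "functional", "negative", threshold = 0.01)
  expect_lt(fit$coefficients[["functional"]], 0)
})

test_that("evaluation correlation is monotone-robust via Spearman", {
  coh <- make_tiny_cohort(n = 24L, n_nodes = 16L, seed = 17,
                          planted = 1:10, effect = 0.7)
  fit <- cpm(coh, "functional", "negative", threshold = 0.05)
  r_direct <- stats::cor(fit$predictions$predicted,
                         fit$predictions$observed, method = "spearman")
  expect_equal(fit$rho, r_direct)
})

test_that("empty-mask folds fall back to training-mean prediction", {
  set.seed(99)
  coh <- make_tiny_cohort(n = 16L, n_nodes = 10L, seed = 99)  # pure noise
  expect_error(cpm(coh, "functional", "negative", threshold = 1e-4),
               "no predictive edges")
  # a mild threshold on noise: some folds empty, predictions still complete
  fit <- tryCatch(
    withCallingHandlers(cpm(coh, "functional", "negative", threshold = 2e-3),
                        warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (!is.null(fit)) expect_true(all(is.finite(fit$predictions$predicted)))
})

test_that("stability-aware selection picks the flat-peak threshold", {
  grid <- seq(1e-4, 0.05, by = 1e-4)
  # oscillating low-accuracy background with one perfectly flat high peak:
  # window variance is zero only where the centered 5-point window sits
  # entirely inside the flat top, i.e. from the third flat grid point on
  rho <- 0.2 + rep_len(c(0.05, -0.05), length(grid))
  rho[grid >= 0.0180 & grid <= 0.0220] <- 0.5
  sel <- select_stable_threshold(grid, rho, window = 5L, quantile = 0.5)
  expect_equal(sel$threshold, 0.0182)  # smallest fully-stable peak threshold
  expect_true(all(sel$table$threshold >= 1e-4 & sel$table$threshold <= 0.05))

  # all-equal landscape: tie-break to the smallest grid threshold
  sel2 <- select_stable_threshold(grid, rep(0.3, length(grid)))
  expect_equal(sel2$threshold, 1e-4)
})

test_that("threshold search runs LOOCV over the grid and respects its bounds", {
  coh <- make_tiny_cohort(n = 20L, n_nodes = 12L, seed = 3,
                          planted = 1:8, effect = 0.8)
  grid <- seq(0.002, 0.05, by = 0.002)
  sel <- optimize_threshold(coh, "functional", "negative", grid = grid)
  expect_true(sel$threshold %in% grid)
  expect_equal(nrow(sel$table), length(grid))
  expect_true(all(diff(sel$table$mean_mask_size) >= 0))  # masks grow with t
  fit <- cpm(coh, "functional", "negative", threshold = NULL, grid = grid)
  expect_equal(fit$threshold, sel$threshold)
  expect_equal(fit$threshold_table$rho, sel$table$rho)
})

test_that("cpm validates its inputs", {
  coh <- make_tiny_cohort(n = 12L, n_nodes = 10L, seed = 1)
  expect_error(cpm(coh, "structural", "negative", threshold = 0.05),
               "structural")
  expect_error(cpm(coh[1:4], "functional", "negative", threshold = 0.05),
               "at least 5")
})
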