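test_that("vectorized association matches the edge-by-edge oracle", {
  set.seed(11)
  n <- 20L
  X <- matrix(rnorm(n * 50), n)
  y <- rnorm(n)
  Z <- cbind(age = rnorm(n, 70, 5), sex = rbinom(n, 1, 0.5))
  got <- edge_behavior_association(X, y, Z)
  ref <- oracle_partial_spearman(X, y, Z)
  expect_equal(got$rho, ref$rho, tolerance = 1e-10)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  expect_equal(got$df, ref$df)
  # and without covariates it reduces to plain Spearman
  got0 <- edge_behavior_association(X, y)
  plain <- apply(X, 2, function(x) stats::cor(x, y, method = "spearman"))
  expect_equal(got0$rho, plain, tolerance = 1e-10)
})

test_that("a monotone edge-behavior relation gives rho = 1", {
  set.seed(2)
  y <- rexp(15)
  X <- cbind(y^3, exp(y), -y)
  a <- edge_behavior_association(X, y)
  expect_equal(a$rho, c(1, 1, -1))
  expect_lt(max(a$p), 1e-10)
})

test_that("association p-values are uniform under the null", {
  set.seed(123)
  X <- matrix(rnorm(30 * 500), 30)
  y <- rnorm(30)
  a <- edge_behavior_association(X, y, cbind(age = rnorm(30), sex = rbinom(30, 1, 0.5)))
  frac <- mean(a$p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.08)
  expect_gt(stats::ks.test(a$p, "punif")$p.value, 0.01)
})

test_that("partial correlation removes a shared covariate", {
  set.seed(5)
  n <- 40L
  conf <- rnorm(n)
  X <- matrix(conf + rnorm(n * 3, sd = 0.05), n, 3)
  y <- conf + rnorm(n, sd = 0.05)
  marginal <- edge_behavior_association(X, y)
  partial <- edge_behavior_association(X, y, cbind(conf = conf))
  expect_gt(min(marginal$rho), 0.9)
  expect_lt(max(abs(partial$rho)), 0.35)
  ref <- oracle_partial_spearman(X, y, cbind(conf))
  expect_equal(partial$rho, ref$rho, tolerance = 1e-10)
})

test_that("association is invariant to monotone behavior transforms", {
  set.seed(8)
  X <- matrix(rnorm(25 * 30), 25)
  y <- rexp(25)
  Z <- cbind(age = rnorm(25))
  a1 <- edge_behavior_association(X, y, Z)
  a2 <- edge_behavior_association(X, log(y) * 3 + 2, Z)
  expect_equal(a1$rho, a2$rho)
  expect_equal(a1$p, a2$p)
})

test_that("association rejects degenerate inputs", {
  X <- matrix(rnorm(12), 4)
  expect_error(edge_behavior_association(X, rep(1, 4)), "constant")
  expect_error(edge_behavior_association(X[1:3, , drop = FALSE], rnorm(3)),
               "4 subjects")
  expect_warning(edge_behavior_association(matrix(rnorm(40), 10), rnorm(10),
                                           cbind(sex = rep(1, 10))),
                 "constant covariate")
})

test_that("edge selection thresholds by p and partitions by sign", {
  assoc <- structure(list(rho = c(0.5, 0.4, -0.6), p = c(0.01, 0.2, 0.03)),
                     class = "edge_association")
  expect_equal(select_edges(assoc, 0.05, "positive"), 1L)
  expect_equal(select_edges(assoc, 0.05, "negative"), 3L)
  # monotone in the threshold; threshold 1 keeps everything, split by sign
  set.seed(1)
  a2 <- edge_behavior_association(matrix(rnorm(600), 20), rnorm(20))
  m1 <- select_edges(a2, 0.01, "positive")
  m2 <- select_edges(a2, 0.05, "positive")
  expect_true(all(m1 %in% m2))
  allpos <- select_edges(a2, 1, "positive")
  allneg <- select_edges(a2, 1, "negative")
  expect_length(intersect(allpos, allneg), 0)
  expect_equal(sort(c(allpos, allneg)), which(a2$rho != 0))
  expect_error(select_edges(a2, 0), "threshold")
})

test_that("summary scores sum masked edges only", {
  edges <- c(0.3, 0.5, -0.2, 0.9)
  expect_equal(summary_score(edges, integer()), 0)
  expect_equal(summary_score(edges, c(1L, 2L)), 0.8)
  perturbed <- edges; perturbed[4] <- 99
  expect_equal(summary_score(perturbed, c(1L, 2L)), 0.8)  # locality
  M <- rbind(edges, 2 * edges)
  expect_equal(summary_score(M, c(1L, 2L)), c(0.8, 1.6), ignore_attr = TRUE)
  expect_error(summary_score(edges, 5L), "bounds")
})
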