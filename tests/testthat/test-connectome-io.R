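test_that("fisher_z is atanh with domain checks", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))   # log-identity oracle
  expect_equal(round(fisher_z(0.5), 6), 0.549306)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_error(fisher_z(1), "\\|r\\| < 1")
  expect_error(fisher_z(-1.2), "\\|r\\| < 1")
})

test_that("volume normalization follows the size-additive rule", {
  cnt <- matrix(c(0, 12, 12, 0), 2)
  out <- volume_normalize(cnt, c(2, 4))
  expect_equal(out[1, 2], 2.0)                # 12 / (2 + 4)
  v <- 3.7
  cnt3 <- matrix(5, 3, 3); diag(cnt3) <- 0
  expect_equal(volume_normalize(cnt3, rep(v, 3))[1, 2], 5 / (2 * v))
  # symmetry preserved, homogeneity in the volumes
  set.seed(1)
  m <- matrix(rpois(25, 20), 5); m <- m + t(m); diag(m) <- 0
  vols <- runif(5, 500, 2000)
  nm <- volume_normalize(m, vols)
  expect_equal(nm, t(nm))
  expect_equal(volume_normalize(m, 3 * vols), nm / 3, ignore_attr = TRUE)
  # alternative rules
  expect_equal(volume_normalize(cnt, c(2, 4), "geometric")[1, 2],
               12 / sqrt(8))
  expect_equal(volume_normalize(cnt, c(2, 4), "mean")[1, 2], 12 / 3)
  expect_equal(attr(nm, "normalization"), "volume_sum")
  expect_error(volume_normalize(cnt, c(0, 4)), "positive")
  expect_error(volume_normalize(-cnt, c(2, 4)), "non-negative")
})

test_that("edge indexing is a bijection in the documented order", {
  expect_equal(nrow(edge_index(268)), 35778L)
  idx3 <- edge_index(3)
  expect_equal(idx3$i, c(1L, 1L, 2L))
  expect_equal(idx3$j, c(2L, 3L, 3L))
  expect_equal(idx3$pos, 0:2)
  idx <- edge_index(9)
  expect_false(anyDuplicated(paste(idx$i, idx$j)) > 0)
  expect_true(all(idx$i < idx$j))
})

test_that("matrix vectorization round-trips exactly", {
  set.seed(3)
  m <- matrix(rnorm(49), 7); m <- (m + t(m)) / 2; diag(m) <- 0
  v <- matrix_to_edges(m)
  expect_length(v, 21L)
  expect_identical(edges_to_matrix(v, 7), m)
  # canonical order agrees with edge_index
  idx <- edge_index(7)
  expect_equal(v[5], m[idx$i[5], idx$j[5]])
})

test_that("ingestion symmetrizes within tolerance and rejects beyond it", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- 0.30; m[2, 1] <- 0.30000001
  got <- ingest_connectome(m, tol = 1e-6)
  expect_equal(got[1, 2], 0.300000005)
  expect_equal(got, t(got))
  expect_equal(ingest_connectome(got), got)    # idempotent

  bad <- m; bad[2, 1] <- 0.32
  expect_error(ingest_connectome(bad, tol = 1e-6), "asymmetry")
  nf <- matrix(0, 3, 3); nf[1, 3] <- nf[3, 1] <- Inf
  expect_error(ingest_connectome(nf), "\\(1, 3\\)")
  d <- diag(5) * 9
  expect_equal(ingest_connectome(d), matrix(0, 5, 5))  # diagonal zeroed
})

test_that("cohorts round-trip through the text formats bit-exactly", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 6, n_nodes = 8,
                                     n_planted = 4, seed = 9))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim$tp1, dir)
  atlas <- read_atlas(file.path(dir, "atlas.csv"))
  got <- load_cohort(paths, file.path(dir, "cohort.csv"), atlas)
  expect_identical(got$edges$functional, sim$tp1$edges$functional)
  expect_identical(got$edges$structural, sim$tp1$edges$structural)
  expect_equal(got$behavior, sim$tp1$behavior)
  expect_equal(got$subjects, sim$tp1$subjects)
  expect_equal(got$atlas$network, sim$tp1$atlas$network)
})

test_that("subject exclusion filters and dimension checks apply on load", {
  sim <- simulate_cohort(cohort_spec(n_subjects = 5, n_nodes = 6,
                                     n_planted = 2, seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_cohort(sim$tp1, dir)
  tab <- utils::read.csv(file.path(dir, "cohort.csv"))
  tab$mean_fd <- c(0.2, 0.31, 0.15, 0.1, 0.25)
  atlas <- read_atlas(file.path(dir, "atlas.csv"))
  got <- suppressMessages(load_cohort(paths, tab, atlas,
                                      filters = "mean_fd <= 0.3"))
  expect_equal(n_subjects(got), 4L)
  excl <- attr(got, "exclusions")
  expect_equal(excl$subject_id, "s002")
  expect_match(excl$reason, "mean_fd")

  wrong <- cpm_atlas(rep_len(canonical_networks(), 9))
  expect_error(suppressMessages(load_cohort(paths, tab, wrong)), "atlas")
})
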