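test_that("block time series carry the planted correlations", {
  comm <- rep(1:4, each = 10)
  X <- generate_parcel_timeseries(comm, rho_in = 0.6, rho_out = 0.1,
                                  n_timepoints = 2000, seed = 11)
  R <- cor(X)
  same <- outer(comm, comm, "==") & upper.tri(R)
  diff <- !outer(comm, comm, "==") & upper.tri(R)
  expect_lt(abs(mean(R[same]) - 0.6), 0.05)
  expect_lt(abs(mean(R[diff]) - 0.1), 0.05)
})

test_that("independent parcels show near-zero sample correlation", {
  X <- generate_parcel_timeseries(rep(1:4, each = 5), rho_in = 0, rho_out = 0,
                                  n_timepoints = 500, seed = 3)
  R <- cor(X)
  expect_lt(mean(abs(R[upper.tri(R)])), 2 / sqrt(500))
})

test_that("time-series generation is bitwise deterministic and rejects bad correlations", {
  a <- generate_parcel_timeseries(rep(1:2, 5), 0.5, 0.1, 50, seed = 9)
  b <- generate_parcel_timeseries(rep(1:2, 5), 0.5, 0.1, 50, seed = 9)
  expect_identical(a, b)
  expect_error(generate_parcel_timeseries(rep(1:2, 5), 0.2, 0.5, 50, 1),
               "rho_in = 0.2, rho_out = 0.5")
  expect_error(generate_parcel_timeseries(rep(1:2, 5), 1.0, 0.1, 50, 1),
               "positive definite")
})

test_that("voxel injection plants the dropout mixture as configured", {
  cfg <- cohort_config(n_subjects = 1, n_parcels = 400, voxels_per_parcel = 25,
                       n_timepoints = 20, seed = 5)
  pts <- generate_parcel_timeseries(make_parcel_table(400)$network_label,
                                    0.35, 0.08, 20, seed = 5)
  sub <- inject_voxel_structure(pts, cfg, seed = 7, dropout_weight = 0.05)
  V <- 400 * 25
  expect_length(sub$true_bad_voxel, V)
  expect_equal(length(unique(sub$parcel_of_voxel)), 400)
  # planted bad count within 3 binomial SDs of V * 0.05
  expect_lt(abs(sum(sub$true_bad_voxel) - V * 0.05),
            3 * sqrt(V * 0.05 * 0.95))
  # dropout voxels carry no parcel signal: their series decorrelate from it
  bad1 <- which(sub$true_bad_voxel)[1]
  p1 <- sub$parcel_of_voxel[bad1]
  good_same <- which(!sub$true_bad_voxel & sub$parcel_of_voxel == p1)[1]
  expect_gt(abs(cor(sub$voxel_timeseries[, good_same], pts[, p1])), 0.5)
  expect_identical(sub, inject_voxel_structure(pts, cfg, seed = 7,
                                               dropout_weight = 0.05))
})

test_that("a single-component mixture designates no dropout voxels", {
  cfg <- cohort_config(n_subjects = 1, n_parcels = 10, voxels_per_parcel = 4,
                       n_timepoints = 15,
                       intensity_components = list(c(1, 100, 5)), seed = 2)
  pts <- matrix(rnorm(150), 15, 10)
  sub <- inject_voxel_structure(pts, cfg, seed = 3)
  expect_false(any(sub$true_bad_voxel))
})

test_that("outcome simulation follows the logistic model", {
  n <- 10000
  feats <- data.frame(age_std = rnorm(n), propofol = 0, midazolam = 0,
                      opioid = 0, clonidine = 0)
  y <- simulate_outcomes(feats, outcome_params(intercept = 0, beta_age = 0,
                                               beta_sedative = rep(0, 4)),
                         seed = 4)
  expect_lt(abs(mean(y) - 0.5), 0.02)
  y2 <- simulate_outcomes(feats, outcome_params(intercept = -20, beta_age = 0,
                                                beta_sedative = rep(0, 4)),
                          seed = 4)
  expect_true(all(y2 == 0))
  one <- data.frame(age_std = 1, propofol = 1, midazolam = 0, opioid = 0,
                    clonidine = 0)
  y3 <- simulate_outcomes(one, outcome_params(intercept = -1, beta_age = 0.5,
                                              beta_sedative = c(0.5, 0, 0, 0)),
                          seed = 1)
  expect_equal(attr(y3, "prob"), 0.5)
  expect_error(simulate_outcomes(one[, -1, drop = FALSE],
                                 outcome_params(), seed = 1), "age_std")
})

test_that("outcome rate calibrates to the planted probabilities", {
  n <- 5000
  feats <- data.frame(age_std = rnorm(n),
                      propofol = rbinom(n, 1, 0.7),
                      midazolam = rbinom(n, 1, 0.3),
                      opioid = rbinom(n, 1, 0.4),
                      clonidine = rbinom(n, 1, 0.1))
  y <- simulate_outcomes(feats, outcome_params(), seed = 12)
  p <- attr(y, "prob")
  expect_lt(abs(mean(y) - mean(p)), 3 * sqrt(sum(p * (1 - p))) / n)
})

test_that("cohort generation is deterministic and respects degenerate settings", {
  cfg <- cohort_config(n_subjects = 3, n_parcels = 28, voxels_per_parcel = 3,
                       n_timepoints = 30, rho_subject_sd = 0, seed = 77)
  ch1 <- generate_cohort(cfg, materialize = TRUE)
  ch2 <- generate_cohort(cfg, materialize = TRUE)
  expect_identical(ch1$covariates, ch2$covariates)
  expect_identical(ch1$subjects, ch2$subjects)
  expect_true(all(ch1$truth$rho_in == cfg$rho_in))

  empty <- generate_cohort(cohort_config(n_subjects = 0, n_parcels = 28,
                                         voxels_per_parcel = 3,
                                         n_timepoints = 30, seed = 1))
  expect_equal(nrow(empty$covariates), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(rho_in = 0.1, rho_out = 0.3), "rho_in > rho_out")
  expect_error(cohort_config(n_timepoints = 5), "n_timepoints")
  expect_error(cohort_config(intensity_components =
                               list(c(0.5, 5, 1), c(0.6, 100, 5))), "sum to 1")
  expect_error(cohort_config(intensity_components =
                               list(c(0.5, 5, 1), c(0.5, 5, 2))),
               "strictly smallest")
})
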