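test_that("intercept-only logistic fit has the closed-form solution", {
  y <- c(rep(1, 7), rep(0, 3))
  f <- fit_logistic(y, matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(f$coefficients[1]), log(7 / 3), tolerance = 1e-8)
  expect_true(f$converged)
  expect_lte(f$loglik, 0)
})

test_that("logistic coefficients and loglik match a grid-search MLE oracle", {
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  x <- c(-1.2, -0.8, -0.3, 0.1, 0.4, 0.9, -0.5, 1.5)
  f <- fit_logistic(y, cbind("(Intercept)" = 1, x = x))
  or <- logistic_grid_mle(y, x)
  expect_equal(unname(f$coefficients), or$coef, tolerance = 1e-6)
  expect_equal(f$loglik, or$loglik, tolerance = 1e-6)
})

test_that("separation and degenerate designs are diagnosed", {
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  x <- c(-4, -3, -2, -1, 1, 2, 3, 4)
  f <- fit_logistic(y, cbind("(Intercept)" = 1, x = x))
  expect_false(f$converged)
  expect_error(fit_logistic(rep(1, 8), cbind(1, x)), "single class")
  expect_error(fit_logistic(y, cbind("(Intercept)" = 1, a = x, b = 2 * x)),
               "aliased column\\(s\\): b")
})

test_that("Nagelkerke R2 anchors and oracle value hold", {
  y <- c(0, 0, 1, 0, 1, 1, 0, 1)
  x <- c(-1.2, -0.8, -0.3, 0.1, 0.4, 0.9, -0.5, 1.5)
  null_f <- fit_logistic(y, matrix(1, 8, 1, dimnames = list(NULL, "(Intercept)")))
  full_f <- fit_logistic(y, cbind("(Intercept)" = 1, x = x))
  expect_equal(nagelkerke_r2(null_f, null_f), 0)
  # hand computation from the two oracle log-likelihoods
  ll0 <- logistic_grid_mle(y, rep(0, 8))$loglik
  ll1 <- logistic_grid_mle(y, x)$loglik
  hand <- (1 - exp((2 / 8) * (ll0 - ll1))) / (1 - exp((2 / 8) * ll0))
  expect_equal(nagelkerke_r2(full_f, null_f), hand, tolerance = 1e-6)
  # a perfectly predicting fit approaches 1
  sep <- fit_logistic(c(0, 0, 0, 0, 1, 1, 1, 1),
                      cbind("(Intercept)" = 1, x = c(-4, -3, -2, -1, 1, 2, 3, 4)))
  expect_gt(nagelkerke_r2(sep, null_f), 0.99)
})

test_that("AUROC matches the all-pairs enumeration oracle, ties included", {
  y <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  s <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8, 0.9, 1.0)
  expect_equal(auroc(s, y), 1)
  expect_equal(auroc(rep(0.5, 10), y), 0.5)
  s2 <- c(0.1, 0.3, 0.3, 0.7, 0.2, 0.3, 0.8, 0.7, 0.9, 0.2)
  pairs <- 0
  for (i in which(y == 1)) for (j in which(y == 0))
    pairs <- pairs + (s2[i] > s2[j]) + 0.5 * (s2[i] == s2[j])
  expect_equal(auroc(s2, y), pairs / 25)
  expect_equal(auroc(s2, y), 1 - auroc(-s2, y))
  skip_if_not_installed("pROC")
  expect_equal(auroc(s2, y),
               as.numeric(pROC::auc(pROC::roc(y, s2, quiet = TRUE))))
})

test_that("AIC follows its definition", {
  f <- list(k_params = 1, loglik = -10)
  expect_equal(aic(f), 22)
  y <- c(0, 1, 0, 1, 1, 0, 1, 0, 1, 1)
  x <- rnorm(10)
  f1 <- fit_logistic(y, cbind("(Intercept)" = 1, x = x))
  expect_equal(aic(f1), 2 * 2 - 2 * f1$loglik, tolerance = 1e-12)
})

test_that("likelihood-ratio test matches the chi-square reference", {
  f_full <- list(k_params = 2, loglik = -5, n = 20)
  f_nest <- list(k_params = 1, loglik = -5, n = 20)
  lrt <- likelihood_ratio_test(f_full, f_nest)
  expect_equal(lrt$statistic, 0)
  expect_equal(lrt$p, 1)
  f_nest2 <- list(k_params = 1, loglik = -5 - 3.841 / 2, n = 20)
  expect_equal(likelihood_ratio_test(f_full, f_nest2)$p, 0.05, tolerance = 1e-3)
  expect_error(likelihood_ratio_test(f_nest, f_full), "more parameters")
})

test_that("Wald test and BH adjustment match hand computations", {
  f <- list(coefficients = c(a = 0, b = 1.96), standard_errors = c(a = 1, b = 1))
  expect_equal(wald_test(f, "a")$p, 1)
  expect_equal(wald_test(f, "b")$p, 2 * pnorm(-1.96), tolerance = 1e-12)
  expect_error(wald_test(f, "zz"), "unknown coefficient")
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("group comparisons reproduce exact references", {
  feats <- data.frame(x = c(1, 2, 3, 10, 11, 12),
                      outcome = c(0, 0, 0, 1, 1, 1))
  gc1 <- group_compare(feats, "x")
  expect_equal(gc1$p, 0.1)                     # exact two-sided, n = 3, 3
  feats2 <- data.frame(x = rep(c(5, 6, 7), 2), outcome = rep(0:1, each = 3))
  expect_gt(group_compare(feats2, "x")$p, 0.99)
  feats3 <- data.frame(flag = rep(c(1, 0), each = 10),
                       outcome = rep(c(1, 0), each = 10))
  gc3 <- group_compare(feats3, "flag", categorical = "flag")
  expect_equal(gc3$statistic, 20)
  expect_lt(gc3$p, 1e-4)
  expect_error(group_compare(data.frame(x = 1:3, outcome = rep(1, 3)), "x"),
               "nonempty")
})

test_that("collinearity screening follows the priority protocol", {
  set.seed(33)
  n <- 60
  base <- rnorm(n)
  mk <- function(r, x = base) r * x + sqrt(1 - r^2) * rnorm(n)
  # |r(medianPC, medianMDZ)| high -> keep median PC only among medians
  f1 <- data.frame(pc_median_DMN = base,
                   mdz_median_DMN = mk(0.9),
                   pc_sd_DMN = mk(0.9), pc_max_DMN = mk(0.9),
                   mdz_sd_DMN = mk(0.9), mdz_max_DMN = mk(0.9))
  expect_equal(screen_collinearity(f1, "DMN"), "pc_median_DMN")
  # medians uncorrelated, max/SD correlated with a median -> keep both medians
  f2 <- data.frame(pc_median_DMN = base,
                   mdz_median_DMN = rnorm(n),
                   pc_sd_DMN = mk(0.9), pc_max_DMN = mk(0.9),
                   mdz_sd_DMN = mk(0.9), mdz_max_DMN = mk(0.9))
  expect_setequal(screen_collinearity(f2, "DMN"),
                  c("pc_median_DMN", "mdz_median_DMN"))
  # all pairwise below threshold -> keep all six
  f3 <- as.data.frame(matrix(rnorm(n * 6), n))
  names(f3) <- c("pc_median_DMN", "mdz_median_DMN", "pc_sd_DMN",
                 "pc_max_DMN", "mdz_sd_DMN", "mdz_max_DMN")
  expect_length(screen_collinearity(f3, "DMN"), 6)
  # a constant summary (the within-module SD of a z-scored metric when the
  # whole network is valid) never enters a model
  f4 <- f3
  f4$mdz_sd_DMN <- 1.009
  expect_false("mdz_sd_DMN" %in% screen_collinearity(f4, "DMN"))
})

test_that("nesting and AIC identities hold across random model fits", {
  set.seed(44)
  for (i in 1:20) {
    n <- 60
    X <- cbind("(Intercept)" = 1, a = rnorm(n), b = rnorm(n))
    y <- rbinom(n, 1, plogis(0.3 * X[, "a"]))
    if (length(unique(y)) < 2) next
    full <- fit_logistic(y, X)
    nest <- fit_logistic(y, X[, 1:2])
    expect_gte(full$loglik, nest$loglik - 1e-9)
    expect_equal(aic(full), 2 * full$k_params - 2 * full$loglik,
                 tolerance = 1e-9)
    lrt <- likelihood_ratio_test(full, nest)
    expect_true(lrt$p >= 0 && lrt$p <= 1)
  }
})

test_that("the model battery mirrors the protocol on a synthetic table", {
  set.seed(55)
  n <- 80
  feats <- data.frame(age = runif(n, 16, 73))
  feats$age_std <- as.numeric(scale(feats$age))
  feats$propofol <- rbinom(n, 1, 0.7); feats$midazolam <- rbinom(n, 1, 0.3)
  feats$opioid <- rbinom(n, 1, 0.4); feats$clonidine <- rbinom(n, 1, 0.1)
  feats$tai <- rbinom(n, 1, 0.5)
  for (nw in yeo7_networks) {
    feats[[paste0("pc_median_", nw)]] <- runif(n, 0.7, 0.85)
    feats[[paste0("mdz_median_", nw)]] <- rnorm(n, 0, 0.2)
    feats[[paste0("pc_sd_", nw)]] <- feats[[paste0("pc_median_", nw)]] * 0.5 +
      rnorm(n, 0, 0.01)
    feats[[paste0("pc_max_", nw)]] <- feats[[paste0("pc_median_", nw)]] +
      abs(rnorm(n, 0.05, 0.01))
    feats[[paste0("mdz_sd_", nw)]] <- runif(n, 0.5, 1.5)
    feats[[paste0("mdz_max_", nw)]] <- feats[[paste0("mdz_median_", nw)]] +
      abs(rnorm(n, 1, 0.2))
  }
  feats$ami <- runif(n, 0.1, 0.3)
  feats$excluded_voxel_pct <- runif(n, 5, 20)
  feats$interhemi_global <- runif(n, 0, 0.3)
  feats$interhemi_dmn <- runif(n, 0, 0.4)
  feats$outcome <- simulate_outcomes(feats, outcome_params(), seed = 9)

  bat <- fit_model_battery(feats)
  expect_true("Nuisance regressors" %in% bat$performance$model)
  expect_true(all(c("AMI + Nuisance regressors",
                    "Excluded voxels + Nuisance regressors",
                    "Inter-hemispheric global (TAI)") %in%
                    bat$performance$model))
  expect_true(all(bat$performance$pseudo_r2 >= 0 &
                    bat$performance$pseudo_r2 <= 1))
  expect_true(all(bat$performance$auroc >= 0 & bat$performance$auroc <= 1))
  # AIC identity on every reported model
  for (nm in names(bat$fits)) {
    f <- bat$fits[[nm]]$fit
    row <- bat$performance[bat$performance$model == nm, ]
    expect_equal(row$aic_value, 2 * f$k_params - 2 * f$loglik,
                 tolerance = 1e-9)
  }
  # adjusted p-values are computed within families and are monotone caps
  cf <- bat$coefficients
  expect_true(all(cf$adj_p >= cf$wald_p - 1e-12))
  expect_true(all(cf$adj_p <= 1))
  con <- cf[cf$family == "connectivity", ]
  expect_equal(con$adj_p, bh_fdr(con$wald_p))
  # the screen keeps medians ahead of max/SD wherever both could enter
  for (nw in yeo7_networks) {
    kept <- bat$selected[[nw]]
    if (any(grepl("pc_(sd|max)", kept)))
      expect_true(paste0("pc_median_", nw) %in% kept ||
                    abs(cor(feats[[paste0("pc_median_", nw)]],
                            feats[[kept[grepl("pc_(sd|max)", kept)][1]]])) <= 0.3)
  }
})
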