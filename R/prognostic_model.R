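#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood binomial fit via `stats::glm.fit` (IRLS, convergence
#' tolerance 1e-10 on the deviance, at most 100 iterations). The fit is
#' flagged non-converged on IRLS failure or quasi-separation (any
#' coefficient beyond +/-15, a bound meaningful on standardized
#' predictors).
#'
#' @param y binary 0/1 response (both classes required).
#' @param X design matrix including an intercept column; must have full
#'   column rank and fewer columns than observations.
#' @return object of class `tbinet_fit`: `coefficients`,
#'   `standard_errors`, `loglik`, `n`, `k_params`, `fitted_probabilities`,
#'   `converged`, `y`.
#' @export
fit_logistic <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  if (length(unique(y)) < 2L)
    stop("response has a single class; logistic fit undefined", call. = FALSE)
  if (nrow(X) <= ncol(X))
    stop("need more observations than parameters", call. = FALSE)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(epsilon = 1e-10, maxit = 100))
  )
  p <- fit$fitted.values
  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  w <- p * (1 - p)
  xtx <- crossprod(X * sqrt(pmax(w, 1e-12)))
  se <- tryCatch(sqrt(diag(solve(xtx))), error = function(e) rep(NA_real_, ncol(X)))
  names(se) <- colnames(X)
  coefs <- fit$coefficients
  converged <- isTRUE(fit$converged) && all(abs(coefs) <= 15)
  structure(list(coefficients = coefs, standard_errors = se,
                 loglik = ll, n = length(y), k_params = ncol(X),
                 fitted_probabilities = p, converged = converged, y = y),
            class = "tbinet_fit")
}

#' Nagelkerke pseudo-R-squared
#'
#' \eqn{R^2 = \frac{1 - \exp\{(2/n)(\ell_0 - \ell_1)\}}{1 - \exp\{(2/n)\ell_0\}}}
#' for a fit with log-likelihood \eqn{\ell_1} against the nested null fit
#' \eqn{\ell_0} on the same response.
#'
#' @param fit,null_fit `tbinet_fit` objects, null nested in fit.
#' @return pseudo-R-squared in \[0, 1\].
#' @export
nagelkerke_r2 <- function(fit, null_fit) {
  if (fit$n != null_fit$n)
    stop("fits are on different samples", call. = FALSE)
  if (fit$loglik < null_fit$loglik - 1e-6)
    stop("full-model log-likelihood below the null's; nesting violated",
         call. = FALSE)
  n <- fit$n
  cs <- 1 - exp((2 / n) * (null_fit$loglik - fit$loglik))
  cs_max <- 1 - exp((2 / n) * null_fit$loglik)
  min(max(cs / cs_max, 0), 1)
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' \eqn{AUROC = P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)}, computed from
#' midranks, so ties are handled exactly.
#'
#' @param scores numeric risk scores.
#' @param y binary 0/1 response (both classes required).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both classes required for AUROC", call. = FALSE)
  r <- rank(scores)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Akaike information criterion of a fit
#'
#' @param fit a `tbinet_fit`.
#' @return `2 k - 2 loglik`.
#' @export
aic <- function(fit) 2 * fit$k_params - 2 * fit$loglik

#' Likelihood-ratio test between nested logistic fits
#'
#' Deviance \eqn{D = 2(\ell_{full} - \ell_{nested})} referred to a
#' chi-square with df = difference in parameter count.
#'
#' @param full,nested `tbinet_fit` objects on the same response.
#' @return list with `statistic`, `df`, `p`.
#' @export
likelihood_ratio_test <- function(full, nested) {
  df <- full$k_params - nested$k_params
  if (df <= 0) stop("full model must have more parameters than the nested one",
                    call. = FALSE)
  if (full$n != nested$n) stop("fits are on different samples", call. = FALSE)
  D <- max(2 * (full$loglik - nested$loglik), 0)
  list(statistic = D, df = df, p = stats::pchisq(D, df, lower.tail = FALSE))
}

#' Wald test for one coefficient
#'
#' Two-sided normal p-value for z = coefficient / standard error.
#'
#' @param fit a `tbinet_fit`.
#' @param name coefficient name.
#' @return list with `z`, `p`.
#' @export
wald_test <- function(fit, name) {
  if (!name %in% names(fit$coefficients))
    stop("unknown coefficient: ", name, call. = FALSE)
  z <- fit$coefficients[[name]] / fit$standard_errors[[name]]
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment within one declared hypothesis family.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @return adjusted p-values (monotone, capped at 1).
#' @export
bh_fdr <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Collinearity screening with the pre-registered priority order
#'
#' Greedy deterministic selection per network: candidates are considered
#' in priority order (median PC, median MDZ, then SD/max of PC, then
#' SD/max of MDZ) and a candidate is dropped iff its absolute Pearson
#' correlation with any already-kept candidate exceeds `threshold`.
#'
#' @param features cohort feature table.
#' @param network network name (e.g. `"DMN"`).
#' @param threshold absolute-correlation cutoff (default 0.3, strict).
#' @return character vector of kept feature column names (possibly empty).
#' @export
screen_collinearity <- function(features, network, threshold = 0.3) {
  cand <- paste0(c("pc_median_", "mdz_median_", "pc_sd_", "pc_max_",
                   "mdz_sd_", "mdz_max_"), network)
  cand <- cand[cand %in% names(features)]
  kept <- character(0)
  for (cc in cand) {
    x <- features[[cc]]
    if (all(is.na(x))) next
    # constant summaries (e.g. the within-module SD of a z-scored metric
    # when every parcel of the network is valid) carry no information
    if (!isTRUE(stats::sd(x, na.rm = TRUE) > 0)) next
    ok <- TRUE
    for (kk in kept) {
      r <- suppressWarnings(stats::cor(x, features[[kk]],
                                       use = "pairwise.complete.obs"))
      if (is.finite(r) && abs(r) > threshold) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, cc)
  }
  kept
}

#' Mann-Whitney / chi-square group comparisons
#'
#' Compares each named variable between outcome groups: continuous
#' variables by the Mann-Whitney U test (normal approximation with tie
#' correction, exact where applicable), binary/categorical variables by
#' Pearson's chi-square on the contingency table (no continuity
#' correction).
#'
#' @param features cohort feature table.
#' @param vars columns to compare.
#' @param group_col grouping column (binary; default `"outcome"`).
#' @param categorical columns among `vars` to treat as categorical.
#' @return data.frame with `variable`, `test`, `statistic`, `p`,
#'   `median_favorable`, `median_unfavorable` (medians NA for categorical
#'   variables).
#' @export
group_compare <- function(features, vars, group_col = "outcome",
                          categorical = character(0)) {
  g <- features[[group_col]]
  if (length(unique(stats::na.omit(g))) < 2L)
    stop("both outcome groups must be nonempty", call. = FALSE)
  rows <- lapply(vars, function(v) {
    x <- features[[v]]
    keep <- !is.na(x) & !is.na(g)
    if (v %in% categorical || is.logical(x)) {
      tb <- table(x[keep], g[keep])
      tst <- suppressWarnings(stats::chisq.test(tb, correct = FALSE))
      data.frame(variable = v, test = "chi-square",
                 statistic = unname(tst$statistic), p = tst$p.value,
                 median_favorable = NA_real_, median_unfavorable = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      tst <- suppressWarnings(stats::wilcox.test(x[keep][g[keep] == 0],
                                                 x[keep][g[keep] == 1]))
      data.frame(variable = v, test = "mann-whitney",
                 statistic = unname(tst$statistic), p = tst$p.value,
                 median_favorable = stats::median(x[keep][g[keep] == 0]),
                 median_unfavorable = stats::median(x[keep][g[keep] == 1]),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

nuisance_design <- function(features) {
  cbind("(Intercept)" = 1,
        age_std = features$age_std,
        propofol = as.numeric(features$propofol),
        midazolam = as.numeric(features$midazolam),
        opioid = as.numeric(features$opioid),
        clonidine = as.numeric(features$clonidine))
}

fit_one_model <- function(features, predictors, response_col = "outcome") {
  use <- c("age_std", "propofol", "midazolam", "opioid", "clonidine",
           predictors, response_col)
  cc <- stats::complete.cases(features[, use, drop = FALSE])
  dat <- features[cc, , drop = FALSE]
  predictors <- predictors[vapply(predictors, function(p)
    isTRUE(stats::sd(dat[[p]]) > 0), logical(1))]
  y <- as.numeric(dat[[response_col]])
  if (length(unique(y)) < 2L) return(NULL)
  Xn <- nuisance_design(dat)
  # constant covariates (e.g. a sedative nobody received in a small cohort)
  # carry no information and would only break the fit
  keep_cols <- c(TRUE, apply(Xn[, -1, drop = FALSE], 2, stats::sd) > 0)
  Xn <- Xn[, keep_cols, drop = FALSE]
  scale_info <- list()
  Xp <- NULL
  if (length(predictors)) {
    Xp <- sapply(predictors, function(p) {
      x <- dat[[p]]
      s <- stats::sd(x)
      scale_info[[p]] <<- list(mean = mean(x), sd = s)
      if (is.finite(s) && s > 0) (x - mean(x)) / s else x - mean(x)
    })
    if (is.null(dim(Xp))) Xp <- matrix(Xp, ncol = length(predictors),
                                       dimnames = list(NULL, predictors))
  }
  X <- if (is.null(Xp)) Xn else cbind(Xn, Xp)
  if (nrow(X) <= ncol(X)) return(NULL)
  full <- fit_logistic(y, X)
  null_fit <- fit_logistic(y, Xn[, "(Intercept)", drop = FALSE])
  nuis <- fit_logistic(y, Xn)
  list(fit = full, nuisance_fit = nuis, null_fit = null_fit,
       n_used = sum(cc), scale_info = scale_info, predictors = predictors)
}

#' Fit the pre-registered prognostic model battery
#'
#' For each of the seven functional networks, screens the six
#' topographical summaries for collinearity ([screen_collinearity()]) and
#' fits outcome ~ nuisance + kept summaries; additionally fits the
#' nuisance-only, AMI, excluded-voxel and (TAI-response) inter-hemispheric
#' models. Continuous predictors are z-scored before fitting; reported
#' coefficients are given on both the standardized and the raw scale.
#' Each model uses complete cases for its own columns. Wald p-values of
#' connectivity predictors are BH-adjusted as one family; the AMI,
#' excluded-voxel and inter-hemispheric families are adjusted separately.
#'
#' @param features cohort feature table (one row per subject).
#' @param alpha significance threshold (default 0.01).
#' @param collinearity_threshold see [screen_collinearity()] (default 0.3).
#' @return list of class `model_battery`: `performance` (model,
#'   pseudo_r2, auroc, aic_value, lrt_p, n_used, converged),
#'   `coefficients` (model, predictor, coefficient, coefficient_std,
#'   wald_p, adj_p, family), `selected` (kept predictors per network),
#'   `alpha`, `fits`.
#' @export
fit_model_battery <- function(features, alpha = 0.01,
                              collinearity_threshold = 0.3) {
  nets <- yeo7_networks
  selected <- lapply(nets, function(nw)
    screen_collinearity(features, nw, collinearity_threshold))
  names(selected) <- nets

  models <- list()
  models[["Nuisance regressors"]] <- fit_one_model(features, character(0))
  for (nw in nets) {
    if (length(selected[[nw]]) == 0L) {
      message("network ", nw, ": no summary survived screening; ",
              "model reduces to nuisance-only")
      next
    }
    models[[paste0(nw, " + Nuisance regressors")]] <-
      fit_one_model(features, selected[[nw]])
  }
  if ("excluded_voxel_pct" %in% names(features))
    models[["Excluded voxels + Nuisance regressors"]] <-
      fit_one_model(features, "excluded_voxel_pct")
  if ("ami" %in% names(features))
    models[["AMI + Nuisance regressors"]] <- fit_one_model(features, "ami")
  if (all(c("tai", "interhemi_global") %in% names(features)))
    models[["Inter-hemispheric global (TAI)"]] <-
      fit_one_model(features, "interhemi_global", response_col = "tai")
  if (all(c("tai", "interhemi_dmn") %in% names(features)))
    models[["Inter-hemispheric DMN (TAI)"]] <-
      fit_one_model(features, "interhemi_dmn", response_col = "tai")

  perf <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    lrt_p <- if (length(m$predictors))
      likelihood_ratio_test(m$fit, m$nuisance_fit)$p else NA_real_
    data.frame(model = nm,
               pseudo_r2 = nagelkerke_r2(m$fit, m$null_fit),
               auroc = auroc(m$fit$fitted_probabilities, m$fit$y),
               aic_value = aic(m$fit),
               lrt_p = lrt_p,
               n_used = m$n_used,
               converged = m$fit$converged,
               stringsAsFactors = FALSE)
  }))

  coef_rows <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    if (!length(m$predictors)) return(NULL)
    fam <- if (grepl("^Inter-hemispheric", nm)) "interhemispheric"
    else if (grepl("^AMI", nm)) "ami"
    else if (grepl("^Excluded", nm)) "excluded_voxels"
    else "connectivity"
    do.call(rbind, lapply(m$predictors, function(p) {
      b_std <- m$fit$coefficients[[p]]
      s <- m$scale_info[[p]]$sd
      data.frame(model = nm, predictor = p,
                 coefficient = if (is.finite(s) && s > 0) b_std / s else b_std,
                 coefficient_std = b_std,
                 wald_p = wald_test(m$fit, p)$p,
                 family = fam, stringsAsFactors = FALSE)
    }))
  }))
  if (!is.null(coef_rows)) {
    coef_rows$adj_p <- NA_real_
    for (fam in unique(coef_rows$family)) {
      i <- coef_rows$family == fam
      coef_rows$adj_p[i] <- bh_fdr(coef_rows$wald_p[i])
    }
  }
  structure(list(performance = perf, coefficients = coef_rows,
                 selected = selected, alpha = alpha, fits = models),
            class = "model_battery")
}
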