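# Feature-level cohort generator used by the statistical calibration tests:
# covariates and a standardized connectivity feature are drawn directly,
# outcomes come from the package's logistic outcome model.

simulate_feature_cohort <- function(n, beta_feature, seed) {
  set.seed(seed)
  feats <- data.frame(
    age_std = rnorm(n),
    propofol = rbinom(n, 1, 0.77), midazolam = rbinom(n, 1, 0.27),
    opioid = rbinom(n, 1, 0.36), clonidine = rbinom(n, 1, 0.09),
    feature = rnorm(n))
  pars <- outcome_params(intercept = -0.1, beta_age = 0.9,
                         beta_feature = beta_feature,
                         feature_name = "feature")
  feats$outcome <- simulate_outcomes(feats, pars, seed = seed + 1)
  feats
}

fit_feature_model <- function(feats) {
  Xn <- cbind("(Intercept)" = 1, age_std = feats$age_std,
              propofol = feats$propofol, midazolam = feats$midazolam,
              opioid = feats$opioid, clonidine = feats$clonidine)
  X <- cbind(Xn, feature = feats$feature)
  list(full = fit_logistic(feats$outcome, X),
       nuis = fit_logistic(feats$outcome, Xn))
}
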