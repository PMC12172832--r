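#' Canonical seven-network labels
#'
#' Network names in template order; parcels carry the integer index 1-7.
#' @export
yeo7_networks <- c("Visual", "Somatomotor", "DorsAttn", "SalVentAttn",
                   "Limbic", "Control", "DMN")

#' Build a parcel metadata table emulating a 400-parcel / 7-network atlas
#'
#' Parcels are split half left- half right-hemisphere; within each
#' hemisphere they are assigned contiguously to the seven networks, so both
#' hemispheres contain every network (as in the Schaefer/Yeo scheme).
#'
#' @param n_parcels total parcel count (even; default 400).
#' @param n_networks number of template communities (default 7).
#' @return data.frame with `parcel_id`, `network_label` (1-based integer),
#'   `network` (name), `hemisphere` ("L"/"R").
#' @export
make_parcel_table <- function(n_parcels = 400L, n_networks = 7L) {
  stopifnot(n_parcels >= 1L, n_networks >= 1L)
  n_left <- as.integer(ceiling(n_parcels / 2))
  n_right <- n_parcels - n_left
  hemi_labels <- function(nh) {
    if (nh == 0L) return(integer(0))
    as.integer(ceiling(seq_len(nh) * n_networks / nh))
  }
  lab <- c(hemi_labels(n_left), hemi_labels(n_right))
  nets <- if (n_networks == 7L) yeo7_networks else paste0("Net", seq_len(n_networks))
  data.frame(
    parcel_id = seq_len(n_parcels),
    network_label = lab,
    network = nets[lab],
    hemisphere = rep(c("L", "R"), c(n_left, n_right)),
    stringsAsFactors = FALSE
  )
}

#' Cohort simulation configuration
#'
#' Bundles the knobs of the synthetic rs-fMRI cohort: graph size, planted
#' block-correlation structure, per-subject coupling spread, the voxel
#' mean-intensity mixture whose lowest-mean component plays the role of
#' susceptibility dropout, and demographic/sedation sampling.
#'
#' @param n_subjects number of subjects.
#' @param n_parcels parcel count (default 400).
#' @param n_networks template community count (default 7).
#' @param voxels_per_parcel gray-matter voxels per parcel (default 25).
#' @param n_timepoints BOLD volumes per subject (default 200, i.e. 500 s at
#'   TR 2.5 s).
#' @param tr_seconds repetition time in seconds (default 2.5).
#' @param rho_in within-network parcel correlation in \[0,1).
#' @param rho_out between-network correlation, `0 <= rho_out < rho_in`.
#' @param rho_subject_sd sd of the per-subject draw around `rho_in`.
#' @param lesion_fraction_range range \[lo,hi\] for the per-subject dropout
#'   mixture weight (fraction of voxels in the dropout component).
#' @param intensity_components list of `c(weight, mean, sd)` triples for the
#'   voxel mean-intensity mixture; the component with the strictly smallest
#'   mean is the dropout component (none is designated if only one
#'   component is given). Weights must sum to 1.
#' @param voxel_noise_sd sd of the i.i.d. Gaussian voxel noise added on top
#'   of (or, for dropout voxels, instead of) the parcel signal.
#' @param age_range uniform sampling range for age in years.
#' @param sedative_rates named Bernoulli rates for the four sedation flags.
#' @param tai_rate Bernoulli rate of the corpus-callosum TAI label.
#' @param seed master seed; per-subject substreams are derived from it.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 44L,
                          n_parcels = 400L,
                          n_networks = 7L,
                          voxels_per_parcel = 25L,
                          n_timepoints = 200L,
                          tr_seconds = 2.5,
                          rho_in = 0.35,
                          rho_out = 0.08,
                          rho_subject_sd = 0.05,
                          lesion_fraction_range = c(0.07, 0.20),
                          intensity_components = list(
                            c(0.05, 5, 1),
                            c(0.35, 90, 6),
                            c(0.40, 100, 6),
                            c(0.20, 110, 6)
                          ),
                          voxel_noise_sd = 1.0,
                          age_range = c(16, 73),
                          sedative_rates = c(propofol = 0.77, midazolam = 0.27,
                                             opioid = 0.36, clonidine = 0.09),
                          tai_rate = 0.5,
                          seed = 20260930L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_parcels = as.integer(n_parcels),
              n_networks = as.integer(n_networks),
              voxels_per_parcel = as.integer(voxels_per_parcel),
              n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
              rho_in = rho_in, rho_out = rho_out, rho_subject_sd = rho_subject_sd,
              lesion_fraction_range = lesion_fraction_range,
              intensity_components = intensity_components,
              voxel_noise_sd = voxel_noise_sd, age_range = age_range,
              sedative_rates = sedative_rates, tai_rate = tai_rate,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$intensity_components) < 1L)
    stop("intensity_components must contain at least one component", call. = FALSE)
  w <- vapply(cfg$intensity_components, `[`, numeric(1), 1L)
  mu <- vapply(cfg$intensity_components, `[`, numeric(1), 2L)
  if (abs(sum(w) - 1) > 1e-8)
    stop("intensity mixture weights must sum to 1", call. = FALSE)
  if (length(mu) > 1L && sum(mu == min(mu)) != 1L)
    stop("the dropout component mean must be strictly smallest", call. = FALSE)
  if (!(cfg$rho_in > cfg$rho_out && cfg$rho_out >= 0))
    stop("require rho_in > rho_out >= 0", call. = FALSE)
  if (cfg$rho_in >= 1) stop("rho_in must be < 1", call. = FALSE)
  if (cfg$n_timepoints < 10L) stop("n_timepoints must be >= 10", call. = FALSE)
  if (cfg$rho_subject_sd < 0) stop("rho_subject_sd must be nonnegative", call. = FALSE)
  lo <- cfg$lesion_fraction_range[1]; hi <- cfg$lesion_fraction_range[2]
  if (!(lo >= 0 && hi <= 1 && lo <= hi))
    stop("lesion_fraction_range must satisfy 0 <= lo <= hi <= 1", call. = FALSE)
  invisible(cfg)
}

#' Outcome model parameters
#'
#' Coefficients of the logistic model generating the dichotomized outcome
#' (1 = unfavorable): intercept, age effect per standardized-age unit, four
#' sedation effects, and optionally an effect of one connectivity summary.
#' The defaults plant an age effect and no connectivity effect, matching a
#' cohort in which connectivity carries no prognostic signal.
#'
#' @param intercept,beta_age,beta_feature scalars.
#' @param beta_sedative length-4 named vector
#'   (propofol, midazolam, opioid, clonidine).
#' @param feature_name feature column driving the outcome, or `"none"`.
#' @return object of class `outcome_params`.
#' @export
outcome_params <- function(intercept = -0.1,
                           beta_age = 0.9,
                           beta_sedative = c(propofol = -0.8, midazolam = -0.3,
                                             opioid = 0.2, clonidine = 0.4),
                           beta_feature = 0,
                           feature_name = "none") {
  stopifnot(is.finite(intercept), is.finite(beta_age), is.finite(beta_feature),
            length(beta_sedative) == 4L, all(is.finite(beta_sedative)))
  names(beta_sedative) <- c("propofol", "midazolam", "opioid", "clonidine")
  structure(list(intercept = intercept, beta_age = beta_age,
                 beta_sedative = beta_sedative, beta_feature = beta_feature,
                 feature_name = feature_name),
            class = "outcome_params")
}

#' Sample parcel time series with planted block-correlation structure
#'
#' Draws T rows from a zero-mean multivariate normal whose covariance is
#' compound-symmetric by community: unit diagonal, `rho_in` within a
#' community, `rho_out` between communities. Sampling uses the exact factor
#' decomposition (shared global factor, per-community factor, idiosyncratic
#' noise), valid - and positive definite - exactly when
#' `0 <= rho_out <= rho_in < 1`.
#'
#' @param community integer community label per parcel.
#' @param rho_in,rho_out planted correlations.
#' @param n_timepoints number of rows T.
#' @param seed integer seed; output is bitwise-reproducible.
#' @return T x P numeric matrix.
#' @export
generate_parcel_timeseries <- function(community, rho_in, rho_out,
                                       n_timepoints, seed) {
  if (!(rho_out >= 0 && rho_in >= rho_out && rho_in < 1))
    stop(sprintf(paste0("block covariance is not positive definite for ",
                        "(rho_in = %g, rho_out = %g); require ",
                        "0 <= rho_out <= rho_in < 1"), rho_in, rho_out),
         call. = FALSE)
  community <- as.integer(community)
  P <- length(community)
  T_ <- as.integer(n_timepoints)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  blocks <- sort(unique(community))
  g_global <- stats::rnorm(T_)
  g_block <- matrix(stats::rnorm(T_ * length(blocks)), T_, length(blocks))
  eps <- matrix(stats::rnorm(T_ * P), T_, P)
  bi <- match(community, blocks)
  sqrt(rho_out) * g_global +
    sqrt(rho_in - rho_out) * g_block[, bi, drop = FALSE] +
    sqrt(1 - rho_in) * eps
}

#' Expand parcel signals into voxel-level data with a dropout mixture
#'
#' Each parcel is expanded into `voxels_per_parcel` gray-matter voxels. A
#' voxel's mixture component is drawn from `intensity_components` (dropout
#' weight optionally overridden by `dropout_weight`); its mean intensity is
#' drawn from that component. Good voxels carry the parcel signal plus
#' i.i.d. Gaussian noise; dropout voxels carry noise only, so they are both
#' low-intensity and connectivity-destroying.
#'
#' @param parcel_ts T x P matrix of parcel signals.
#' @param cfg a [cohort_config()].
#' @param seed integer seed.
#' @param dropout_weight optional override of the dropout component weight
#'   (remaining weights rescaled); used to vary lesion load across subjects.
#' @return list of class `subject_voxels`: `voxel_mean_intensity`,
#'   `voxel_timeseries` (T x V), `parcel_of_voxel`, `graymatter_mask`,
#'   `true_bad_voxel` (simulation truth, never consumed by the pipeline).
#' @export
inject_voxel_structure <- function(parcel_ts, cfg, seed, dropout_weight = NULL) {
  comps <- cfg$intensity_components
  if (length(comps) < 1L) stop("intensity_components is empty", call. = FALSE)
  if (cfg$voxels_per_parcel < 1L) stop("voxels_per_parcel must be >= 1", call. = FALSE)
  w <- vapply(comps, `[`, numeric(1), 1L)
  mu <- vapply(comps, `[`, numeric(1), 2L)
  sd_ <- vapply(comps, `[`, numeric(1), 3L)
  drop_idx <- if (length(comps) > 1L) which.min(mu) else NA_integer_
  if (!is.null(dropout_weight) && !is.na(drop_idx)) {
    w[-drop_idx] <- w[-drop_idx] * (1 - dropout_weight) / sum(w[-drop_idx])
    w[drop_idx] <- dropout_weight
  }
  P <- ncol(parcel_ts); T_ <- nrow(parcel_ts)
  V <- P * cfg$voxels_per_parcel
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  parcel_of_voxel <- rep(seq_len(P), each = cfg$voxels_per_parcel)
  comp <- sample.int(length(comps), V, replace = TRUE, prob = w)
  intensity <- stats::rnorm(V, mu[comp], sd_[comp])
  bad <- if (is.na(drop_idx)) rep(FALSE, V) else comp == drop_idx
  ts <- parcel_ts[, parcel_of_voxel, drop = FALSE]
  ts[, bad] <- 0
  ts <- ts + matrix(stats::rnorm(T_ * V, sd = cfg$voxel_noise_sd), T_, V)
  structure(list(voxel_mean_intensity = intensity,
                 voxel_timeseries = ts,
                 parcel_of_voxel = parcel_of_voxel,
                 graymatter_mask = rep(TRUE, V),
                 true_bad_voxel = bad),
            class = "subject_voxels")
}

#' Draw dichotomized outcomes from the logistic outcome model
#'
#' P(unfavorable) = logistic(intercept + beta_age * age_std +
#' beta_sedative . flags \[+ beta_feature * feature\]); outcomes are
#' independent Bernoulli draws, deterministic given the seed.
#'
#' @param features data.frame with columns `age_std`, `propofol`,
#'   `midazolam`, `opioid`, `clonidine`, and the feature column named by
#'   `params$feature_name` (unless `"none"`).
#' @param params an [outcome_params()].
#' @param seed integer seed.
#' @return integer vector (1 = unfavorable) with attribute `"prob"` holding
#'   the planted probabilities.
#' @export
simulate_outcomes <- function(features, params, seed) {
  need <- c("age_std", names(params$beta_sedative))
  if (!identical(params$feature_name, "none")) need <- c(need, params$feature_name)
  missing_cols <- setdiff(need, names(features))
  if (length(missing_cols))
    stop("missing covariate column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  eta <- params$intercept + params$beta_age * features$age_std
  for (s in names(params$beta_sedative))
    eta <- eta + params$beta_sedative[[s]] * as.numeric(features[[s]])
  if (!identical(params$feature_name, "none"))
    eta <- eta + params$beta_feature * features[[params$feature_name]]
  p <- stats::plogis(eta)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  y <- as.integer(stats::runif(length(p)) < p)
  attr(y, "prob") <- p
  y
}

#' Generate a synthetic cohort plan
#'
#' Draws per-subject coupling strengths, lesion loads, demographics,
#' sedation and TAI flags, and per-subject RNG substreams from the master
#' seed. Voxel data are materialized lazily with [generate_subject()] so
#' that large cohorts can be processed one subject at a time; with
#' `materialize = TRUE` all subjects are generated up front. Outcomes are
#' drawn immediately when `outcome$feature_name == "none"`; otherwise they
#' depend on computed connectivity features and are filled in by the
#' pipeline after feature assembly (`outcome` column is NA until then).
#'
#' @param cfg a [cohort_config()].
#' @param outcome an [outcome_params()].
#' @param materialize generate all subjects' voxel data now (default FALSE).
#' @return list of class `cohort`: `cfg`, `outcome_params`, `parcel_table`,
#'   `covariates` (data.frame), `truth` (planted per-subject parameters),
#'   `subject_seeds`, and `subjects` (list, possibly empty).
#' @export
generate_cohort <- function(cfg, outcome = outcome_params(), materialize = FALSE) {
  validate_cohort_config(cfg)
  n <- cfg$n_subjects
  parcel_table <- make_parcel_table(cfg$n_parcels, cfg$n_networks)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)
  subject_seeds <- sample.int(2100000000L, max(n, 1L))[seq_len(n)]
  outcome_seed <- sample.int(2100000000L, 1L)
  rho_i <- pmin(pmax(stats::rnorm(n, cfg$rho_in, cfg$rho_subject_sd),
                     cfg$rho_out), 0.95)
  lesion <- stats::runif(n, cfg$lesion_fraction_range[1], cfg$lesion_fraction_range[2])
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sed <- vapply(cfg$sedative_rates,
                function(r) as.integer(stats::runif(n) < r),
                integer(n))
  if (n == 1L) sed <- matrix(sed, nrow = 1L, dimnames = list(NULL, names(cfg$sedative_rates)))
  tai <- as.integer(stats::runif(n) < cfg$tai_rate)
  covariates <- data.frame(subject = seq_len(n), age = age)
  if (n > 0L) covariates <- cbind(covariates, as.data.frame(sed)) else {
    for (s in names(cfg$sedative_rates)) covariates[[s]] <- integer(0)
  }
  covariates$tai <- tai
  covariates$age_std <- if (n > 1L && stats::sd(age) > 0)
    as.numeric(scale(age)) else rep(0, n)
  covariates$outcome <- rep(NA_integer_, n)
  if (identical(outcome$feature_name, "none") && n > 0L) {
    covariates$outcome <- simulate_outcomes(covariates, outcome, outcome_seed)
  }
  truth <- data.frame(subject = seq_len(n), rho_in = rho_i,
                      rho_out = rep(cfg$rho_out, n),
                      lesion_fraction = lesion, seed = subject_seeds)
  ch <- structure(list(cfg = cfg, outcome_params = outcome,
                       parcel_table = parcel_table, covariates = covariates,
                       truth = truth, subject_seeds = subject_seeds,
                       outcome_seed = outcome_seed, subjects = list()),
                  class = "cohort")
  if (materialize && n > 0L)
    ch$subjects <- lapply(seq_len(n), function(i) generate_subject(ch, i))
  ch
}

#' Materialize one subject's voxel-level data from a cohort plan
#'
#' @param cohort a [generate_cohort()] result.
#' @param i subject index.
#' @return a `subject_voxels` object (see [inject_voxel_structure()]).
#' @export
generate_subject <- function(cohort, i) {
  stopifnot(i >= 1L, i <= cohort$cfg$n_subjects)
  cfg <- cohort$cfg
  tr <- cohort$truth[i, ]
  pts <- generate_parcel_timeseries(cohort$parcel_table$network_label,
                                    tr$rho_in, tr$rho_out,
                                    cfg$n_timepoints, tr$seed)
  inject_voxel_structure(pts, cfg, seed = tr$seed + 1L,
                         dropout_weight = tr$lesion_fraction)
}
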