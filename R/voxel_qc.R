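#' Fit a univariate Gaussian mixture to voxel mean intensities by EM
#'
#' Expectation-maximization for a k-component univariate normal mixture.
#' Components are initialized at k evenly spaced quantiles of the data with
#' equal weights and the pooled (population) variance; iteration stops when
#' the relative log-likelihood change drops below `tol` or after
#' `max_iter` iterations. The log-likelihood is non-decreasing across
#' iterations. Hard assignment is by maximum posterior responsibility.
#'
#' @param intensities numeric vector of per-voxel mean intensities.
#' @param k number of mixture components (>= 1; fewer distinct data values
#'   than k is an error).
#' @param seed accepted for interface stability; the quantile
#'   initialization is deterministic so no randomness is consumed.
#' @param max_iter,tol EM controls.
#' @return object of class `gmm_fit`: `k`, `weights`, `means`, `variances`,
#'   `assignment` (1-based component index per voxel), `loglik`,
#'   `loglik_trace`, `n_iter`.
#' @export
fit_intensity_gmm <- function(intensities, k, seed = NULL,
                              max_iter = 500L, tol = 1e-8) {
  x <- as.numeric(intensities)
  if (any(!is.finite(x))) stop("intensities must be finite", call. = FALSE)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (length(unique(x)) < k)
    stop(sprintf("need at least k = %d distinct values, got %d",
                 k, length(unique(x))), call. = FALSE)
  n <- length(x)
  if (k == 1L) {
    v <- mean((x - mean(x))^2)
    ll <- sum(stats::dnorm(x, mean(x), sqrt(v), log = TRUE))
    return(structure(list(k = 1L, weights = 1, means = mean(x), variances = v,
                          assignment = rep(1L, n), loglik = ll,
                          loglik_trace = ll, n_iter = 0L),
                     class = "gmm_fit"))
  }
  means <- as.numeric(stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE))
  vars <- rep(mean((x - mean(x))^2), k)
  w <- rep(1 / k, k)
  var_floor <- max(1e-12 * stats::var(x), 1e-300)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  resp <- NULL
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, means[j], sqrt(vars[j])),
                   numeric(n))
    tot <- rowSums(dens)
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    ll_trace <- c(ll_trace, ll)
    resp <- dens / tot
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    nk <- colSums(resp)
    nk[nk == 0] <- .Machine$double.xmin
    w <- nk / n
    means <- colSums(resp * x) / nk
    vars <- pmax(colSums(resp * (outer(x, means, "-")^2)) / nk, var_floor)
  }
  structure(list(k = k, weights = w, means = means, variances = vars,
                 assignment = max.col(resp, ties.method = "first"),
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace, n_iter = length(ll_trace)),
            class = "gmm_fit")
}

#' Sweep the mixture order k and report fit diagnostics
#'
#' Fits k = 1..k_max mixtures and tabulates log-likelihood, parameter count
#' and BIC — a diagnostic to support the (manual) choice of k, not an
#' automatic selector; the pipeline default is k = 4.
#'
#' @inheritParams fit_intensity_gmm
#' @param k_max largest k to fit (default 5).
#' @return data.frame with columns `k`, `loglik`, `n_params`, `bic`.
#' @export
gmm_k_sweep <- function(intensities, k_max = 5L, max_iter = 500L, tol = 1e-8) {
  n <- length(intensities)
  rows <- lapply(seq_len(k_max), function(k) {
    f <- fit_intensity_gmm(intensities, k, max_iter = max_iter, tol = tol)
    np <- 3L * k - 1L
    data.frame(k = k, loglik = f$loglik, n_params = np,
               bic = -2 * f$loglik + np * log(n))
  })
  do.call(rbind, rows)
}

#' Flag voxels in the low-intensity mixture tail
#'
#' Marks all voxels hard-assigned to the smallest-mean component as bad,
#' provided a lower-bound tail is actually present: the smallest mean must
#' fall below `presence_ratio` times the weight-averaged mean of the
#' remaining components. With k = 1, or when the tail is absent, no voxel
#' is flagged.
#'
#' @param fit a [fit_intensity_gmm()] result.
#' @param presence_ratio tail-presence cutoff (default 0.5).
#' @return logical bad-voxel mask.
#' @export
detect_lower_tail <- function(fit, presence_ratio = 0.5) {
  stopifnot(inherits(fit, "gmm_fit"))
  n <- length(fit$assignment)
  if (fit$k == 1L) return(rep(FALSE, n))
  j0 <- which.min(fit$means)
  w_rest <- fit$weights[-j0]
  rest_mean <- sum(w_rest * fit$means[-j0]) / sum(w_rest)
  if (fit$means[j0] < presence_ratio * rest_mean) fit$assignment == j0
  else rep(FALSE, n)
}

#' Aggregate good voxels to parcel time series and apply the parcel rule
#'
#' Each parcel's time series is the arithmetic mean over its surviving
#' (gray-matter, non-bad) voxels. A parcel is excluded when strictly more
#' than `exclusion_threshold` of its gray-matter voxels are bad (a parcel
#' at exactly 50% bad is retained), or when it has no gray-matter voxels at
#' all. The excluded-voxel percentage is computed over gray-matter voxels.
#'
#' @param data a `subject_voxels` object.
#' @param bad_voxel_mask logical mask from [detect_lower_tail()].
#' @param parcel_table parcel metadata from [make_parcel_table()].
#' @param exclusion_threshold bad-voxel fraction above which a parcel is
#'   dropped (default 0.5, strict inequality).
#' @param tr_seconds repetition time attached to the parcel series.
#' @return list with `parcel_ts` (a [parcel_ts()] object) and `qc` (class
#'   `voxel_qc_result`: `bad_voxel_mask`, `excluded_fraction` in percent,
#'   `valid_parcel_mask`, `parcel_bad_fraction`).
#' @export
aggregate_parcels <- function(data, bad_voxel_mask, parcel_table,
                              exclusion_threshold = 0.5, tr_seconds = 2.5) {
  stopifnot(length(bad_voxel_mask) == length(data$parcel_of_voxel))
  gm <- data$graymatter_mask
  P <- nrow(parcel_table)
  T_ <- nrow(data$voxel_timeseries)
  series <- matrix(NA_real_, T_, P)
  bad_frac <- rep(NA_real_, P)
  valid <- rep(FALSE, P)
  for (p in seq_len(P)) {
    vox <- which(data$parcel_of_voxel == parcel_table$parcel_id[p] & gm)
    if (length(vox) == 0L) {
      warning(sprintf("parcel %d has no gray-matter voxels; marked invalid",
                      parcel_table$parcel_id[p]), call. = FALSE)
      next
    }
    bad_frac[p] <- mean(bad_voxel_mask[vox])
    if (bad_frac[p] > exclusion_threshold) next
    good <- vox[!bad_voxel_mask[vox]]
    series[, p] <- rowMeans(data$voxel_timeseries[, good, drop = FALSE])
    valid[p] <- TRUE
  }
  qc <- structure(list(bad_voxel_mask = bad_voxel_mask,
                       excluded_fraction = 100 * mean(bad_voxel_mask[gm]),
                       valid_parcel_mask = valid,
                       parcel_bad_fraction = bad_frac),
                  class = "voxel_qc_result")
  pts <- parcel_ts(series, parcel_table, valid = valid, tr_seconds = tr_seconds)
  list(parcel_ts = pts, qc = qc)
}

#' Run the full voxel QC stage on one subject
#'
#' Convenience wrapper: GMM fit on gray-matter mean intensities (default
#' k = 4), lower-tail detection, parcel aggregation.
#'
#' @inheritParams aggregate_parcels
#' @param k mixture order (default 4).
#' @param presence_ratio see [detect_lower_tail()].
#' @return as [aggregate_parcels()], plus the `gmm_fit` under `$gmm`.
#' @export
voxel_qc <- function(data, parcel_table, k = 4L, presence_ratio = 0.5,
                     exclusion_threshold = 0.5, tr_seconds = 2.5) {
  fit <- fit_intensity_gmm(data$voxel_mean_intensity[data$graymatter_mask], k)
  mask_gm <- detect_lower_tail(fit, presence_ratio)
  mask <- rep(FALSE, length(data$graymatter_mask))
  mask[data$graymatter_mask] <- mask_gm
  out <- aggregate_parcels(data, mask, parcel_table,
                           exclusion_threshold = exclusion_threshold,
                           tr_seconds = tr_seconds)
  out$gmm <- fit
  out
}
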