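#' Parcel time-series container
#'
#' A T x P matrix of parcel-mean BOLD signals with parcel metadata and a
#' per-parcel validity mask; invalid parcels are excluded from every
#' downstream computation.
#'
#' @param data T x P numeric matrix (columns may be NA for invalid parcels).
#' @param parcel_table metadata with `parcel_id`, `network_label`,
#'   `hemisphere` (see [make_parcel_table()]).
#' @param valid logical vector length P (default all TRUE).
#' @param tr_seconds repetition time in seconds.
#' @return object of class `parcel_ts`.
#' @export
parcel_ts <- function(data, parcel_table, valid = NULL, tr_seconds = 2.5) {
  data <- as.matrix(data)
  P <- ncol(data)
  stopifnot(nrow(parcel_table) == P, nrow(data) >= 10L, tr_seconds > 0)
  if (is.null(valid)) valid <- rep(TRUE, P)
  stopifnot(length(valid) == P)
  structure(list(data = data,
                 parcel_id = parcel_table$parcel_id,
                 network_label = parcel_table$network_label,
                 hemisphere = parcel_table$hemisphere,
                 valid = as.logical(valid),
                 tr_seconds = tr_seconds),
            class = "parcel_ts")
}

#' Detrend and band-pass parcel time series
#'
#' Each valid column has its least-squares linear trend removed, then an
#' ideal (frequency-domain) band-pass is applied: Fourier bins with
#' (folded) frequency inside `[low_hz, high_hz]` are kept, all others
#' zeroed. With `low_hz > 0` the DC bin is removed, so every output column
#' has mean (numerically) zero.
#'
#' @param ts a [parcel_ts()] object.
#' @param low_hz,high_hz pass-band edges in Hz (defaults 0.008 and 0.1);
#'   `high_hz` must not exceed the Nyquist frequency `1/(2 tr)`.
#' @return a [parcel_ts()] with filtered columns.
#' @export
clean_timeseries <- function(ts, low_hz = 0.008, high_hz = 0.1) {
  stopifnot(inherits(ts, "parcel_ts"))
  nyq <- 1 / (2 * ts$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz))
    stop("require 0 <= low_hz < high_hz", call. = FALSE)
  if (high_hz > nyq + 1e-12)
    stop(sprintf("high_hz = %g exceeds the Nyquist frequency %g Hz at TR %g s",
                 high_hz, nyq, ts$tr_seconds), call. = FALSE)
  T_ <- nrow(ts$data)
  tt <- seq_len(T_)
  X <- cbind(1, tt)
  freqs <- (seq_len(T_) - 1) / (T_ * ts$tr_seconds)
  folded <- pmin(freqs, 1 / ts$tr_seconds - freqs)
  keep <- folded >= low_hz - 1e-12 & folded <= high_hz + 1e-12
  out <- ts$data
  for (p in which(ts$valid)) {
    x <- ts$data[, p]
    x <- x - X %*% qr.coef(qr(X), x)
    xf <- stats::fft(x)
    xf[!keep] <- 0
    out[, p] <- Re(stats::fft(xf, inverse = TRUE)) / T_
  }
  ts$data <- out
  ts
}

#' Pearson connectivity matrix
#'
#' Full pairwise Pearson correlations between valid parcel time series:
#' symmetric, unit diagonal, entries in \[-1, 1\]. Valid parcels with zero
#' temporal variance are demoted to invalid with a warning; rows/columns of
#' invalid parcels are NA.
#'
#' @param ts a [parcel_ts()] object.
#' @return object of class `conn_matrix`: `r` (P x P), `valid`,
#'   `parcel_id`, `network_label`, `hemisphere`.
#' @export
pearson_connectivity <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  valid <- ts$valid
  sds <- apply(ts$data[, valid, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    zv <- which(valid)[sds == 0]
    warning(sprintf("parcel(s) %s have zero variance; marked invalid",
                    paste(ts$parcel_id[zv], collapse = ", ")), call. = FALSE)
    valid[zv] <- FALSE
  }
  P <- length(valid)
  r <- matrix(NA_real_, P, P)
  idx <- which(valid)
  if (length(idx) >= 2L) {
    rv <- stats::cor(ts$data[, idx, drop = FALSE])
    rv <- (rv + t(rv)) / 2
    diag(rv) <- 1
    r[idx, idx] <- rv
  } else if (length(idx) == 1L) r[idx, idx] <- 1
  structure(list(r = r, valid = valid, parcel_id = ts$parcel_id,
                 network_label = ts$network_label, hemisphere = ts$hemisphere),
            class = "conn_matrix")
}

#' Positive-part weighted adjacency over valid parcels
#'
#' Keeps only positive correlations — the graph on which participation
#' coefficient, module-degree z-score and Louvain operate — and zeroes the
#' diagonal. Returns a plain matrix restricted to valid parcels, with
#' parcel ids as dimnames.
#'
#' @param cm a [pearson_connectivity()] result.
#' @return numeric matrix over valid parcels.
#' @export
positive_part <- function(cm) {
  stopifnot(inherits(cm, "conn_matrix"))
  idx <- which(cm$valid)
  W <- pmax(cm$r[idx, idx, drop = FALSE], 0)
  diag(W) <- 0
  dimnames(W) <- list(cm$parcel_id[idx], cm$parcel_id[idx])
  W
}

#' Median inter-hemispheric connectivity
#'
#' Median of the signed Pearson correlations over all valid
#' (left-parcel, right-parcel) pairs, optionally restricted to one
#' functional network (both parcels must belong to it). Computed on the
#' signed matrix: the positive-part restriction applies to graph metrics
#' only.
#'
#' @param cm a [pearson_connectivity()] result.
#' @param network_filter optional integer network label (1-7).
#' @return the median, or NA (with a warning) when no pair exists.
#' @export
interhemispheric_median <- function(cm, network_filter = NULL) {
  stopifnot(inherits(cm, "conn_matrix"))
  sel <- cm$valid
  if (!is.null(network_filter)) sel <- sel & cm$network_label == network_filter
  li <- which(sel & cm$hemisphere == "L")
  ri <- which(sel & cm$hemisphere == "R")
  if (length(li) == 0L || length(ri) == 0L) {
    warning("no valid left/right parcel pair for inter-hemispheric median",
            call. = FALSE)
    return(NA_real_)
  }
  stats::median(cm$r[li, ri, drop = FALSE])
}
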