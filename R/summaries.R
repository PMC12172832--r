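#' Per-network topographical summaries of a nodal metric
#'
#' Median, maximum and sample (n-1) standard deviation of a nodal metric
#' within each functional network, over valid parcels only. Networks with
#' fewer than `min_nodes` valid parcels get NA summaries (missing, never
#' zero); with a single valid node median = max = value and the SD is NA.
#'
#' @param values nodal metric vector, one entry per valid node.
#' @param network_label integer network label per valid node.
#' @param n_networks number of networks (default 7).
#' @param min_nodes minimum valid parcels for a summary to exist
#'   (default 3).
#' @return data.frame with `network_label`, `network`, `n_valid`, `median`,
#'   `max`, `sd`.
#' @export
summarize_network <- function(values, network_label, n_networks = 7L,
                              min_nodes = 3L) {
  stopifnot(length(values) == length(network_label))
  if (length(network_label) && (min(network_label) < 1L || max(network_label) > n_networks))
    stop("network labels must lie in 1..n_networks", call. = FALSE)
  nets <- if (n_networks == 7L) yeo7_networks else paste0("Net", seq_len(n_networks))
  out <- data.frame(network_label = seq_len(n_networks), network = nets,
                    n_valid = 0L, median = NA_real_, max = NA_real_,
                    sd = NA_real_, stringsAsFactors = FALSE)
  for (g in seq_len(n_networks)) {
    v <- values[network_label == g]
    out$n_valid[g] <- length(v)
    if (length(v) < min_nodes) next
    out$median[g] <- stats::median(v)
    out$max[g] <- max(v)
    out$sd[g] <- if (length(v) >= 2L) stats::sd(v) else NA_real_
  }
  out
}

#' Assemble the per-subject feature row
#'
#' One row per subject: for each network and each of PC / MDZ the median,
#' max and SD (columns `pc_median_DMN`, `mdz_sd_Control`, ...), plus the
#' adjusted mutual information between the subject's Louvain partition and
#' the template, the excluded-voxel percentage, the global and DMN
#' inter-hemispheric medians, and the covariates. Missing network
#' summaries propagate as NA and are never imputed.
#'
#' @param qc a `voxel_qc_result`.
#' @param pc,mdz nodal metric vectors over valid parcels.
#' @param network_label integer labels over valid parcels.
#' @param louvain_partition integer labels over valid parcels.
#' @param template_partition integer labels over valid parcels.
#' @param interhemi_global,interhemi_dmn inter-hemispheric medians.
#' @param covariates one-row data.frame (age, sedation flags, outcome, ...).
#' @param n_networks,min_nodes see [summarize_network()].
#' @return one-row data.frame of class `subject_features`.
#' @export
assemble_features <- function(qc, pc, mdz, network_label,
                              louvain_partition, template_partition,
                              interhemi_global, interhemi_dmn,
                              covariates, n_networks = 7L, min_nodes = 3L) {
  if (length(pc) != length(network_label) || length(mdz) != length(network_label))
    stop("metric vectors and network labels have inconsistent parcel counts",
         call. = FALSE)
  if (length(louvain_partition) != length(template_partition) ||
      length(louvain_partition) != length(network_label))
    stop("partitions and network labels have inconsistent parcel counts",
         call. = FALSE)
  row <- list()
  for (metric in c("pc", "mdz")) {
    sm <- summarize_network(get(metric), network_label,
                            n_networks = n_networks, min_nodes = min_nodes)
    for (g in seq_len(nrow(sm))) {
      row[[paste(metric, "median", sm$network[g], sep = "_")]] <- sm$median[g]
      row[[paste(metric, "max", sm$network[g], sep = "_")]] <- sm$max[g]
      row[[paste(metric, "sd", sm$network[g], sep = "_")]] <- sm$sd[g]
    }
  }
  row$ami <- adjusted_mutual_information(louvain_partition, template_partition)
  row$excluded_voxel_pct <- qc$excluded_fraction
  row$n_valid_parcels <- sum(qc$valid_parcel_mask)
  row$interhemi_global <- interhemi_global
  row$interhemi_dmn <- interhemi_dmn
  out <- as.data.frame(row, stringsAsFactors = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  class(out) <- c("subject_features", class(out))
  out
}
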