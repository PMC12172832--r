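#!/usr/bin/env Rscript
# Stage 2: run every subject through voxel QC, connectivity estimation and
# graph metrics, and write the per-subject feature table.
#
# Per subject: GMM (k = 4) on voxel mean intensities -> lower-tail removal
# -> strict >50% parcel exclusion -> detrend + 0.008-0.1 Hz band-pass ->
# Pearson connectivity -> positive-edge graph -> PC / MDZ against the
# 7-network template -> Louvain (resolution 1) + AMI vs template ->
# inter-hemispheric medians. Voxel data are regenerated from the recorded
# substream seeds, so this stage only needs results/cohort_truth.json.

library(tbinet)

out_dir <- "results"
truth <- jsonlite::read_json(file.path(out_dir, "cohort_truth.json"),
                             simplifyVector = TRUE)
ic <- truth$config$cohort$intensity_components
ic <- if (is.matrix(ic) || is.data.frame(ic)) {
  lapply(seq_len(nrow(ic)), function(i) as.numeric(ic[i, ]))
} else {
  lapply(ic, as.numeric)
}
truth$config$cohort$intensity_components <- ic
cfg <- run_config(
  cohort = do.call(cohort_config, c(
    truth$config$cohort[c("n_subjects", "n_parcels", "n_networks",
                          "voxels_per_parcel", "n_timepoints", "tr_seconds",
                          "rho_in", "rho_out", "rho_subject_sd",
                          "voxel_noise_sd", "tai_rate", "seed")],
    list(lesion_fraction_range = unlist(truth$config$cohort$lesion_fraction_range),
         intensity_components = truth$config$cohort$intensity_components,
         age_range = unlist(truth$config$cohort$age_range),
         sedative_rates = stats::setNames(
           unlist(truth$config$cohort$sedative_rates),
           c("propofol", "midazolam", "opioid", "clonidine"))))))
cohort <- generate_cohort(cfg$cohort, cfg$outcome)

rows <- vector("list", cfg$cohort$n_subjects)
for (i in seq_len(cfg$cohort$n_subjects)) {
  subj <- generate_subject(cohort, i)
  rows[[i]] <- suppressWarnings(compute_subject_features(
    subj, cohort$parcel_table, cfg,
    covariates = cohort$covariates[i, , drop = FALSE],
    louvain_seed = cohort$subject_seeds[i] %% 1000000L + 1L))
  cat(sprintf("subject %2d: %5.1f%% voxels excluded, %d/%d parcels valid, AMI %.3f\n",
              i, rows[[i]]$excluded_voxel_pct, rows[[i]]$n_valid_parcels,
              cfg$cohort$n_parcels, rows[[i]]$ami))
}
features <- do.call(rbind, rows)
write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)

cat(sprintf("\nFeature table: %d subjects x %d columns -> %s\n",
            nrow(features), ncol(features),
            file.path(out_dir, "features.csv")))
cat(sprintf("Median excluded voxels %.2f%%; median AMI %.3f; median DMN PC %.3f\n",
            median(features$excluded_voxel_pct), median(features$ami),
            median(features$pc_median_DMN)))
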