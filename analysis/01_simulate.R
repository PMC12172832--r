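#!/usr/bin/env Rscript
# Stage 1: define the synthetic cohort and write its plan to results/.
#
# The cohort emulates a 44-patient neurocritical-care rs-fMRI study: 400
# cortical parcels in 7 functional networks, 200 BOLD volumes at TR 2.5 s
# (500 s of data), block-structured inter-parcel correlations, a
# low-intensity dropout voxel mixture, and demographics/sedation flags with
# ICU-like rates. Outcomes follow a logistic model on age + sedation; by
# default no connectivity effect is planted.

library(tbinet)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 20260930L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- run_config(cohort = cohort_config(seed = seed))
cohort <- generate_cohort(cfg$cohort, cfg$outcome)

write.csv(cohort$parcel_table, file.path(out_dir, "parcel_metadata.csv"),
          row.names = FALSE)
write.csv(cohort$covariates, file.path(out_dir, "covariates.csv"),
          row.names = FALSE)
# full truth record: planted per-subject coupling, lesion load, substreams
jsonlite::write_json(
  list(config = tbinet:::unclass_recursive(cfg), truth = cohort$truth),
  file.path(out_dir, "cohort_truth.json"),
  auto_unbox = TRUE, digits = NA, dataframe = "columns", pretty = TRUE)

cat(sprintf("Cohort plan written: %d subjects, %d parcels, %d timepoints\n",
            cfg$cohort$n_subjects, cfg$cohort$n_parcels,
            cfg$cohort$n_timepoints))
cat(sprintf("Planted rho_in median %.3f (rho_out %.2f); lesion load %.2f-%.2f\n",
            median(cohort$truth$rho_in), cfg$cohort$rho_out,
            min(cohort$truth$lesion_fraction),
            max(cohort$truth$lesion_fraction)))
cat(sprintf("Unfavorable outcomes: %d / %d\n",
            sum(cohort$covariates$outcome == 1), nrow(cohort$covariates)))
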