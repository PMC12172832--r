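#!/usr/bin/env Rscript
# Stage 3: group comparisons and the pre-registered logistic model battery.
#
# Reads results/features.csv, compares favorable vs unfavorable groups
# (Mann-Whitney U / chi-square), screens the six topographical summaries
# per network at |r| > 0.3 with the median-PC-first priority, fits
# outcome ~ nuisance (age + 4 sedatives) + kept summaries per network plus
# the AMI, excluded-voxel and (TAI-response) inter-hemispheric models, and
# writes the three report tables.

library(tbinet)

out_dir <- "results"
features <- read.csv(file.path(out_dir, "features.csv"))

battery <- fit_model_battery(features, alpha = 0.01,
                             collinearity_threshold = 0.3)
cmp_vars <- c(grep("^(pc|mdz)_median_", names(features), value = TRUE),
              "ami", "excluded_voxel_pct", "age",
              "propofol", "midazolam", "opioid", "clonidine")
group_cmp <- group_compare(features, cmp_vars,
                           categorical = c("propofol", "midazolam",
                                           "opioid", "clonidine"))

run <- structure(list(features = features, battery = battery,
                      group_comparisons = group_cmp,
                      config = run_config(), cohort_truth = NULL),
                 class = "pipeline_run")
write_report(run, out_dir)

cat("Kept predictors per network after collinearity screening:\n")
for (nw in names(battery$selected))
  cat(sprintf("  %-12s %s\n", nw,
              if (length(battery$selected[[nw]]))
                paste(battery$selected[[nw]], collapse = ", ") else "(none)"))
cat("\nModel performance:\n")
print(battery$performance[, c("model", "pseudo_r2", "auroc", "aic_value",
                              "lrt_p")], digits = 3, row.names = FALSE)
sig <- battery$coefficients$adj_p < battery$alpha
cat(sprintf("\nConnectivity predictors significant at alpha = %.2f after FDR: %d of %d\n",
            battery$alpha, sum(sig, na.rm = TRUE), length(sig)))
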