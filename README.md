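# tbinet — meso-scale brain-network prognostics for critically ill TBI

`tbinet` implements an end-to-end resting-state fMRI prognostics analysis
for critically ill traumatic brain injury (TBI) cohorts, together with a
synthetic BOLD cohort generator so the whole protocol runs and is tested
without any patient data.

**Who it is for.** Researchers in clinical network neuroscience who want a
tested, reproducible implementation of the "topographical summary"
prognostics protocol: voxel-level quality control for susceptibility
dropout, parcel-level functional connectivity, meso-scale graph measures
summarized per functional network, and a pre-registered logistic-regression
analysis of dichotomized outcome.

## The measures at the core

For a positive weighted graph with strengths
κ<sub>is</sub> (node *i* into community *s*) and κ<sub>i</sub> = Σ<sub>s</sub> κ<sub>is</sub>:

- **Participation coefficient** P<sub>i</sub> = 1 − Σ<sub>s</sub> (κ<sub>is</sub>/κ<sub>i</sub>)²
- **Module-degree z-score** z<sub>i</sub> = (κ<sub>i</sub><sup>own</sup> − μ<sub>m</sub>)/σ<sub>m</sub>
  (population SD within *i*'s module)
- **Modularity** Q = (1/2m) Σ<sub>ij</sub> [w<sub>ij</sub> − γ k<sub>i</sub>k<sub>j</sub>/2m] δ(c<sub>i</sub>,c<sub>j</sub>),
  maximized by a seeded, deterministic **Louvain** implementation (γ = 1)
- **Adjusted mutual information** AMI = (MI − E[MI]) / (H̄ − E[MI]) with
  the hypergeometric E[MI], scoring each subject's detected community
  structure against the healthy 7-network template

Around them: GMM-based voxel QC (k = 4, lowest-mean tail removal, strict
>50% parcel exclusion), detrending + 0.008–0.1 Hz ideal band-pass, Pearson
connectivity with positive-edge graphs, per-network median/max/SD
summaries, inter-hemispheric medians, and logistic models with age +
sedation nuisance regressors, |r| > 0.3 collinearity screening, Nagelkerke
R², AUROC, AIC, likelihood-ratio and Wald tests, and Benjamini–Hochberg
FDR at α = 0.01. See `vignettes/tbinet-methods.Rmd` for the full account.

## Worked example

The analysis is organized as three drivers over the package functions:

```sh
Rscript analysis/01_simulate.R     # cohort plan -> results/
Rscript analysis/02_features.R     # QC + connectivity + graph metrics -> features.csv
Rscript analysis/03_models.R       # group tests + model battery -> report tables
```

`01_simulate` defines a 44-subject cohort (400 parcels, 7 networks, 200
time points at TR 2.5 s) and prints:

```
Cohort plan written: 44 subjects, 400 parcels, 200 timepoints
Planted rho_in median 0.353 (rho_out 0.08); lesion load 0.08-0.19
Unfavorable outcomes: 16 / 44
```

`02_features` regenerates each subject from its recorded seed and runs the
full per-subject pipeline:

```
subject 44:  12.3% voxels excluded, 400/400 parcels valid, AMI 1.000

Feature table: 44 subjects x 56 columns -> results/features.csv
Median excluded voxels 13.40%; median AMI 0.948; median DMN PC 0.775
```

The excluded-voxel percentages sit in the low teens (the planted lesion
load), AMI near 1 says the planted community structure is essentially
perfectly recovered from 200 time points, and median PC ≈ 0.78 reflects
how much positive strength leaks across networks at the planted coupling.

`03_models` screens predictors and fits the battery:

```
Kept predictors per network after collinearity screening:
  Control      pc_median_Control, mdz_median_Control
  DMN          pc_median_DMN, mdz_median_DMN, mdz_sd_DMN
  ...

Model performance:
                                 model pseudo_r2 auroc aic_value   lrt_p
                   Nuisance regressors    0.2073 0.732      62.5      NA
             DMN + Nuisance regressors    0.2831 0.772      65.5 0.39660
             AMI + Nuisance regressors    0.3180 0.781      60.1 0.03582
  ...

Connectivity predictors significant at alpha = 0.01 after FDR: 0 of 23
```

Because the default cohort plants an age + sedation effect but **no**
connectivity effect, the nuisance model already discriminates (AUROC
0.73) and, as expected under the null, no connectivity summary survives
FDR at α = 0.01 — the maxima/SDs are largely screened out beforehand by
the |r| > 0.3 rule. Planting an effect does flip the answer: with
`outcome_params(intercept = -58.2, feature_name = "pc_median_DMN",
beta_feature = 75)` — about 1.9 log-odds per SD of the feature, centered
via the intercept — a 100-subject run yields a DMN-model likelihood-ratio
p of 2.4e-10 and lifts AUROC from 0.67 (nuisance) to 0.90.

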