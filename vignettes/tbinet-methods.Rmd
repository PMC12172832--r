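---
title: "Meso-scale network prognostics for critically ill TBI: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meso-scale network prognostics for critically ill TBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Resting-state fMRI connectivity is a candidate prognostic marker in
critically ill traumatic brain injury (TBI). The analysis implemented here
asks whether *topographical summaries* of two meso-scale graph measures —
the participation coefficient (PC) and the within-module degree z-score
(MDZ), summarized as the median, maximum and SD per canonical functional
network — discriminate between patients with favorable and unfavorable
dichotomized outcomes (Glasgow Outcome Scale 1–3 vs 4–5), after adjusting
for age and sedation. A complementary question is whether the *deviation*
of a patient's empirically detected community structure from the healthy
7-network template, quantified by adjusted mutual information (AMI),
carries prognostic information.

Because no patient data are distributed, the package pairs the analysis
pipeline with a synthetic cohort generator that plants exactly the
statistical structure the pipeline assumes, so that every stage is testable
and the full protocol can be exercised end to end.

## Pipeline stages and their models

### Voxel quality control

Critically ill TBI patients carry hemorrhages, air and monitoring devices
that produce susceptibility-related signal dropout. QC works on the
*mean intensity over time* of each gray-matter voxel: a univariate
Gaussian mixture (default `k = 4`, configurable; a `k = 1..5` sweep is
available as a diagnostic via `gmm_k_sweep()`) is fitted by EM, and all
voxels hard-assigned to the smallest-mean component are removed, provided
that component is genuinely a *lower tail*. "Tail present" is
operationalized as: smallest mean `<` `presence_ratio` (default 0.5) times
the weight-averaged mean of the remaining components. This rule is our
interpretation of an informally stated criterion and is configurable.

EM details (the literature leaves them open): initialization at `k` evenly
spaced quantiles with equal weights and the pooled variance; convergence at
relative log-likelihood change below 1e-8; at most 500 iterations; a
variance floor of 1e-12 times the data variance guards against component
collapse. The quantile initialization is deterministic, so no RNG is
consumed.

A parcel is excluded when *strictly more than* 50% of its gray-matter
voxels are bad — a parcel at exactly half bad is retained — and retained
parcels get the arithmetic mean of their surviving voxels as their time
series. The percentage of excluded voxels (over gray-matter voxels) is
itself a per-subject feature.

### Temporal cleaning and connectivity

Each parcel series is linearly detrended (least squares) and band-passed
to 0.008–0.1 Hz with an ideal frequency-domain filter: FFT bins whose
folded frequency lies inside the band are kept, all others zeroed. An
ideal filter was chosen because it is the simplest defensible
implementation and analytically transparent (a sinusoid inside the band is
preserved essentially exactly; outside, removed); the original toolbox
filter is not bit-reproducible anyway. Band edges are inclusive.
Requesting a high edge above Nyquist (`1/(2·TR)`, 0.2 Hz at TR 2.5 s) is
an error.

Connectivity is the full Pearson correlation matrix over valid parcels.
Graph metrics operate on its positive part (negative edges zeroed,
diagonal zeroed); the *signed* matrix is used for the inter-hemispheric
medians, because the positive-edge restriction belongs to the graph
measures, not to connectivity summaries. Inter-hemispheric connectivity is
the median over *all* valid left×right parcel pairs (not only homotopic
pairs), optionally restricted to one network (both parcels in it).

### Graph measures

With positive strengths $\kappa_{is}$ from node $i$ into community $s$ and
$\kappa_i = \sum_s \kappa_{is}$:

* **Participation coefficient** $P_i = 1 - \sum_s (\kappa_{is}/\kappa_i)^2$,
  with $P_i = 0$ for isolated nodes by convention.
* **Module-degree z-score** $z_i = (\kappa_i^{own} - \mu_m)/\sigma_m$ with
  the *population* (divide-by-n) SD over the nodes of $i$'s module;
  singleton or zero-spread modules give $z_i = 0$. MDZ uses the same
  positive-edge graph as PC; the source protocol is explicit about the
  restriction only for PC, so this choice is configurable in principle and
  noted as an interpretation.
* **Modularity**
  $Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \gamma\frac{k_ik_j}{2m}\right]\delta(c_i,c_j)$,
  null model including $i=j$ terms, resolution $\gamma = 1$ throughout.
* **Louvain**: two-phase local moving + aggregation. Tie-breaking: nodes
  are visited in an order shuffled by the seed and the *first strictly
  improving* move (gain > 1e-12) is accepted; aggregation keeps
  self-loops; convergence when a full pass moves nothing. $Q$ is
  non-decreasing across passes and the final value is recomputed
  independently from the returned partition.
* **AMI** with the hypergeometric (permutation-model) expected mutual
  information, normalized by the *mean* of the two entropies (the common
  modern default; `"max"` is available by flag since the source names no
  variant). A vanishing denominator returns 0.

One subtle consequence of z-scoring MDZ *within* modules while the
template communities coincide with the seven networks: the per-network SD
of MDZ is nearly deterministic (≈ $\sqrt{n/(n-1)}$) whenever all of a
network's parcels are valid. Constant summaries carry no prognostic
information and are dropped at the screening stage.

### Topographical summaries and the feature row

Per network (Visual, Somatomotor, DorsAttn, SalVentAttn, Limbic, Control,
DMN) and per metric: median, max and sample (n−1) SD over valid parcels.
A network with fewer than `min_nodes = 3` valid parcels gets missing
summaries (never zero, never imputed); models use complete cases per
model. The template partition for a subject is the 7-network template
restricted to that subject's valid parcels.

### The pre-registered statistical protocol

Candidates for each network's model are screened deterministically at
|Pearson r| > 0.3 in priority order — median PC, median MDZ, then SD/max
of PC, then SD/max of MDZ — dropping a candidate iff it correlates beyond
the threshold with an already-kept one. Models are multivariate logistic
regressions with age (z-scored) and four sedation flags (propofol,
midazolam, opioid, clonidine) as nuisance regressors. Fitting is IRLS
(deviance tolerance 1e-10, max 100 iterations); continuous predictors are
z-scored before fitting for numerical stability (the protocol's own
scaling is unstated), and coefficients are reported on both scales.
Quasi-separation is flagged when IRLS fails or any coefficient exceeds
±15 on the standardized scale.

Reported per model: Nagelkerke pseudo-$R^2$
($[1-e^{(2/n)(\ell_0-\ell_1)}]/[1-e^{(2/n)\ell_0}]$ against the
intercept-only null), AUROC (midrank Mann–Whitney formulation, exact under
ties), AIC ($2k - 2\ell$), and the likelihood-ratio test against the
nuisance-only model. Per predictor: Wald p (two-sided normal) and
Benjamini–Hochberg adjusted p. FDR families follow the
one-family-per-question reading: all connectivity-summary predictors
across the seven network models form one family; the AMI model, the
excluded-voxel model and the inter-hemispheric models are separate
families. Significance is declared at α = 0.01. Group-level contrasts
(feature by outcome) use the Mann–Whitney U test for continuous variables
and Pearson's chi-square (no continuity correction) for categorical ones.

The inter-hemispheric models differ from the others in their response:
they regress the presence of traumatic axonal injury (TAI) in the corpus
callosum — a binary radiological label supplied as data, never computed —
on the global and DMN inter-hemispheric medians plus the nuisance set.

## The synthetic cohort generator

The generator's defaults *are* the study conditions: 44 subjects, 400
parcels in 7 networks split over two hemispheres, 200 time points at TR
2.5 s (500 s of usable data), 25 gray-matter voxels per parcel.

* **Parcel signals** are zero-mean multivariate normal with a
  compound-symmetric block covariance: correlation `rho_in = 0.35` within
  a network, `rho_out = 0.08` between networks, drawn by the exact factor
  construction (valid and positive definite iff
  `0 ≤ rho_out ≤ rho_in < 1`). This is the simplest model carrying
  exactly the community structure the metrics measure. Per-subject
  coupling varies as N(0.35, 0.05²), clipped to `[rho_out, 0.95]`.
* **Voxels** add i.i.d. N(0, 1) noise to their parcel's signal; mean
  intensities come from a 4-component mixture (weights .05/.35/.40/.20,
  means 5/90/100/110) whose smallest-mean component is the dropout
  component: those voxels are noise-only (connectivity-destroying) and
  low-intensity, which is exactly what the QC stage assumes. The
  per-subject dropout weight is drawn uniformly from
  `lesion_fraction_range = [0.07, 0.20]`, putting the cohort's
  excluded-voxel percentages in the low-teens range typical of severe
  susceptibility artifact loads.
* **Covariates**: age uniform on 16–73; sedation flags Bernoulli with
  ICU-like rates (propofol .77, midazolam .27, opioid .36, clonidine
  .09); TAI Bernoulli(.5), independent of everything else.
* **Outcomes** are Bernoulli draws from
  $\mathrm{logit}^{-1}(\beta_0 + \beta_{age}\,\mathrm{age}_z + \beta_{sed}\cdot\mathrm{flags} \,[+\, \beta_f\, f])$
  with defaults $\beta_0 = -0.1$, $\beta_{age} = 0.9$,
  $\beta_{sed} = (-0.8, -0.3, 0.2, 0.4)$ and **no connectivity effect**
  ($\beta_f = 0$): the source study found none, so the default cohort is a
  null cohort with a real age/sedation signal. Any feature column can be
  made outcome-driving via `outcome_params(feature_name=, beta_feature=)`;
  since such features exist only after the QC/metrics stages, the pipeline
  draws outcomes after feature assembly in that case. The effect sizes
  are this package's choice — no empirical effect estimates exist to copy.
* **Reproducibility**: one master seed spawns per-subject substream seeds,
  so any subject can be regenerated in isolation and results do not depend
  on processing order.

### What the generator does *not* emulate

No hemodynamic response, head motion, physiological noise, spatial
autocorrelation within parcels, scanner drift (beyond what detrending
removes), or spatially structured lesions — dropout voxels are sampled
i.i.d. rather than clustered around hemorrhages. Real parcels also do not
follow an exact compound-symmetric block covariance, and injured brains
deviate from the healthy template far more than these synthetic subjects
do (synthetic AMI vs template comes out ≈ 0.95, i.e. near-perfect
template recovery). Passing tests therefore demonstrate the *correctness of the
computations and protocol logic* under the assumed data model — not that
the measures are prognostic, nor how the pipeline behaves under real
acquisition artifacts.

## Numerical choices and degenerate inputs

* Zero-variance parcels are demoted to invalid with a warning before
  correlation; invalid parcels are absent from every graph, partition,
  metric vector and median.
* The band-pass keeps edge bins inclusively; detrending makes column
  means exactly zero once the DC bin is removed.
* PC of an isolated node is 0; MDZ of a singleton or zero-spread module
  is 0; AMI with a degenerate denominator is 0.
* An empty candidate set after screening reduces a model to
  nuisance-only (logged); constant predictors are dropped before fitting;
  designs with more parameters than observations are skipped rather than
  fitted.
* Exact 50% bad parcels are *retained* (the exclusion reading is strict).

## Problem sizes used in testing

The shipped test-and-verification setup runs, per invocation: the
44-subject default cohort at full 400-parcel scale for the acceptance
script; 200 random graphs (n ≤ 20) against literal-formula oracles;
exhaustive modularity enumeration on 50 graphs of n ≤ 8; 100 seeded
Louvain runs on an 80-node planted 4-block graph; QC on one 10,000-voxel
subject with 5% planted dropout; 1,000 feature-level null cohorts (n = 100
each) for likelihood-ratio calibration, 200 replicates at n = 400 for
coefficient recovery (planted β = 1.0) and 200 at n = 200 for power
(β = 1.5, α = 0.01). The statistical calibration deliberately simulates at
the *feature* level — covariates, a standardized feature and
package-drawn outcomes — because re-running the voxel pipeline per
replicate exercises nothing additional about the statistics.

## Known limitations

* The lower-tail "presence" rule and the FDR family partition are
  interpretations of informally stated protocol elements; both are
  configurable.
* The Louvain implementation targets correctness and determinism, not
  speed; it is comfortable at 400 nodes but is pure R.
* Whether the intensity GMM should see raw or normalized intensities is
  unresolved; per-subject raw intensities are assumed.
* AMI normalization ("mean" vs "max" entropy) is unspecified in the
  protocol; "mean" is the default here.
* The generator's outcome model is logistic by construction, matching the
  analysis model; the pipeline is not tested against misspecified outcome
  links.
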