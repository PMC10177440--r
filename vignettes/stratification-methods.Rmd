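---
title: "Methods: simulating and comparing surveillance stratification rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and comparing surveillance stratification rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umstrat)
```

## The problem

About half of uveal melanoma (UM) patients eventually develop metastases,
most often hepatic, and periodic liver imaging of "high-risk" patients can
detect them before symptoms. Which patients count as high-risk depends on
the prognostic system used: a continuous model-based 5-year
metastasis-associated-mortality (MAM) score, ordinal AJCC tumour stage, or
monosomy 3 alone. Each system, once a threshold is fixed, becomes a binary
stratification rule whose performance against the 5-year endpoint (death
from, or detection of, metastasis within 5 years of primary treatment) can
be summarised by sensitivity, specificity, predictive values and the
fraction of the population enrolled in surveillance. The package's core
question is comparative: at *equal sensitivity*, which rule has better
specificity — i.e. catches the same cases with fewer unnecessary scans —
and what is that worth in scans and money?

## The generative model

The original cohort is confidential, so the package ships a generator
(`cohort_config()` / `generate_cohort()`) that emulates its published
statistical structure rather than its records. The model, per patient:

1. **Subgroup.** With probability 723/1047 the patient has a chromosome 3
   result ("tested"); otherwise not. The untested subgroup corresponds to
   patients with tumours too small to biopsy or who declined — so it is
   not missing at random: it has smaller tumours and lower risk.
2. **Latent risk.** The true probability $p$ of the 5-year endpoint is
   drawn from a subgroup-specific two-component Beta mixture
   (low-risk/high-risk components). Means are pinned to the subgroup
   incidences (0.34 tested, 0.14 untested; overall 0.28).
3. **Endpoint.** $Y \sim \mathrm{Bernoulli}(p)$.
4. **Scores.** The full-information score is $p$ itself — *perfect
   calibration*. No score-error model is published for the full channel,
   and this choice makes the AUC a pure function of the mixture, which is
   what makes calibration tractable. Degraded channels (score without
   chromosome 3; score without any genetics) are logit-space
   shrink-and-jitter copies:
   $\mathrm{logit}(q) = m + k\,(\mathrm{logit}(p) - m) + \varepsilon$,
   $\varepsilon \sim N(0, \sigma^2)$, with $m$ the subgroup mean log-odds
   and $k = 0.85$. Shrinkage is monotone and therefore AUC-preserving; the
   dispersion $\sigma$ alone tunes the AUC loss. A dispersion of 0
   switches the channel off (identity), so "no degradation" is exactly
   reproducible. Untested patients carry the degraded no-chr3 value in
   *both* score columns — their observed score cannot use a chromosome 3
   result.
5. **Monosomy 3.** Among tested tumours, monosomy is assigned with
   probability $\mathrm{logit}^{-1}(1.0 + 1.5\,(\mathrm{logit}(p) -
   \mathrm{logit}(0.34)))$, calibrated so ~50% of tested tumours are
   monosomic while keeping the marker strongly associated with outcome.
6. **Stage.** A noisy copy of latent risk,
   $u = \mathrm{logit}^{-1}(\mathrm{logit}(p) + N(0, 1.8^2))$, is cut at
   fixed boundaries into the six stages I–IIIC, then displaced by one
   category with probability 0.05 (clamped at the extremes). Stage is
   *not* computed from tumour dimensions: the staging grid is not part of
   this analysis, and what matters downstream is only that stage is an
   ordinal, coarser, noisier correlate of risk.
7. **Covariates.** Age, sex, tumour diameter and height, ciliary body
   involvement and extraocular extension are decorative for the analysis
   (no rule uses them) but are generated — diameter tied to latent risk so
   untested tumours are smaller — to exercise the CSV schema and the
   eligibility filter.

### Calibration of the defaults

The free parameters (mixture shapes, $\sigma$'s, stage noise and
cutpoints, monosomy intercept) were fixed once, by Monte-Carlo grid search
at large $n$, against these targets: overall full-score AUC ≈ 0.88;
degraded-score AUC within the untested subgroup ≈ 0.79; no-genetics AUC
≈ 0.84; subgroup incidences 0.34/0.14 (hence overall ≈ 0.28); ~50%
monosomy among tested tumours; stage fractions skewed low
(0.29/0.27/0.20/0.13/0.08/0.03) so that stage ≥ IIA enrols ~71% of the
population and operates near 95% sensitivity / 38% specificity. The frozen
defaults achieve (2·10⁶-draw check): AUC 0.880 / 0.789 / 0.840, incidence
0.278, monosomy 49.9%, stage rule 95.1%/38.2% at 71.1% surveillance. The
within-tested AUC of the frozen mixture is 0.898, at the upper end of the
plausible band; it is the price of hitting the *overall* 0.88 with a
31% untested subgroup whose scores are heavily degraded.

What the generator does **not** emulate: correlation between covariates
and scores beyond latent risk; time-to-event structure (the endpoint is
binary); any dependence between these patients and the cohort on which the
scoring models were trained; the exact published histogram of scores. A
passing test suite therefore demonstrates that the *methods* behave
correctly under realistic structure, not that the synthetic cohort is
exchangeable with the real one — the dataset-specific accuracy numbers
(AUCs, table sensitivities/specificities) are calibration targets, never
assertions about real data.

## Stratification rules

Threshold comparisons are inclusive (`score ≥ t`, `stage ≥ cut`): the
published tables use "MAM ≥ x" notation, and where prose says "higher
than", the table notation wins. Stage order is the six listed categories
I < IIA < IIB < IIIA < IIIB < IIIC. Scores on a 0–100 scale should be
normalised to [0, 1] at ingestion so one threshold mechanism serves all
models. The monosomy-3 rule enrols both monosomic and *untested* patients
— the safe default for a missing strong marker. The dual-threshold rule
applies one cut to tested patients' full score and a more conservative cut
to untested patients' degraded score; it equals the corresponding
single-threshold rule within each subgroup by construction.

## Accuracy statistics: numerical choices

- **Clopper–Pearson** intervals use the Beta-quantile closed form, with
  lower = 0 at $k = 0$ and upper = 1 at $k = n$. They are exact
  (conservative): simulated coverage is ≥ nominal.
- **Empirical ROC**: operating points at every distinct observed score as
  an inclusive threshold plus the (0,0) corner; ties between a positive
  and a negative score count ½, and trapezoidal integration over the
  tie-merged curve equals the Mann–Whitney statistic (asserted to 1e-12
  against explicit pair counting). AUC confidence intervals use the DeLong
  variance with a normal interval clipped to [0, 1] — one method chosen
  for internal consistency with the paired test.
- **DeLong paired test**: structural components per positive/negative via
  midranks; two-sided p from the standard normal. Zero paired variance
  with equal AUCs (e.g. literally identical scores) returns statistic 0,
  p = 1; zero variance with unequal AUCs is an error, since it indicates
  non-exchangeable inputs rather than a boundary case.
- **Holm adjustment** delegates to `stats::p.adjust`; the family is the
  set of comparisons actually run, recorded in the pipeline log.
- **Report rounding**: whole percents with halves up, matching the
  published tables; rounding happens only at the formatting layer.
- **Impact arithmetic**: expected counts are rounded to whole patients
  *per strategy first*, then differenced — the only order that reproduces
  all the published savings figures simultaneously. If rounding breaks the
  population total, the largest-remainder cell is adjusted and the result
  flagged. Costs and savings are truncated (floored) to whole pounds; the
  published £41,877 (= ⌊310 × 135.09⌋) shows truncation, not rounding,
  and it is applied uniformly. When two strategies differ in sensitivity,
  the scan delta still counts only false-positive scans and the extra
  missed cases are reported separately (`extra_fn`) — the published
  comparisons all hold sensitivity fixed, so this extension is flagged in
  the output rather than silent.

## The matched-sensitivity comparison

The analysis' central claim is that the continuous score catches the same
cases as the stage rule while scanning fewer unaffected patients. On one
simulated cohort this is operationalised by
`matched_sensitivity_comparison()`: within each chromosome-3 subgroup, the
available score channel is thresholded at the largest value attaining the
stage rule's sensitivity *in that subgroup* (the dual-threshold decision
algorithm), and the pooled specificity is compared with the stage rule's.
This subgroup-matched form is the package's restatement of the published
decision algorithm, and it dominates the stage rule in ~98% of replicate
cohorts (mean specificity 0.52 vs 0.38).

A simpler form — one global threshold matched to the stage rule's overall
realised sensitivity — also dominates strongly in expectation (+0.12 mean
specificity) but only in ~90% of individual replicates: when the stage
rule draws an unusually high sensitivity by sampling noise (0.96–0.98), a
single global cut is forced into the heavy Gaussian tail of the untested
subgroup's degraded scores. That tail is pinned by the within-untested AUC
target (shrinkage cannot change AUC, so the jitter dispersion is fully
determined), so this is a genuine property of the study conditions, not a
tuning artefact; both formulations are tested, the global one at the
expectation level.

## Pipeline, I/O and determinism

Cohort CSVs serialise scores with 17 significant digits, so write→read
round trips are bit-exact; the only permitted missing token in analysis
input is `chr3_status = "unknown"`. Configurations serialise as YAML with
unknown keys rejected. The eligibility filter never fails: it partitions
records into retained and excluded, one reason per exclusion (iris
melanoma; inadequate follow-up without an observed endpoint; each missing
covariate group), mirroring the study's inclusion rules. `run_pipeline()`
is a deterministic function of its configuration: every CSV it writes is
byte-identical across same-seed runs. The run log records the seed, a
config fingerprint and the Holm family, and carries wall-clock timestamps
— it is the one output excluded from the byte-identity contract.

## Problem sizes

The test suite runs at the study's native scale where the check demands it
(200 replicate cohorts of n = 1047 for calibration recovery; 500
null-simulation replicates of n = 2000 for the DeLong p-value uniformity
check; 5000 replicates for interval coverage; 2000 bootstrap resamples of
a 300-record fixture for the variance check) and at reduced scale
(n = 250–800, 30–40 replicates) for structural and expectation-level
properties, keeping the full suite under a minute.

## Known limitations

- The binary 5-year endpoint discards time-to-event information; nothing
  here models metastases detected after 5 years.
- Scores are generator outputs or user-supplied columns; the package does
  not reimplement the underlying prognostic models, so it cannot score
  real patients from covariates.
- The impact model counts scans and imaging tariffs only — no treatment
  pathways, QALYs or compliance effects; it is an accounting identity on
  top of (sensitivity, specificity), not an economic evaluation.
- Calibration matches first-order targets (incidences, AUCs, operating
  points); higher-order features of the real cohort (exact score
  histogram, covariate joint distribution) are not matched.
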