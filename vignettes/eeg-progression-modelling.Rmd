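---
title: "Modelling EEG-based disease progression in prodromal synucleinopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling EEG-based disease progression in prodromal synucleinopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsustain)
library(dplyr)
```

## The problem

Isolated REM sleep behavior disorder (iRBD) is a prodromal state of the
Lewy body diseases: a large fraction of patients eventually phenoconvert
to Parkinson's disease, dementia with Lewy bodies, or multiple system
atrophy, but on widely varying time scales. Resting-state EEG is a cheap,
repeatable window on the cortical dysfunction that precedes conversion —
classically a slowing of the spectrum (rising delta/theta power) and
regional changes in beta power.

`eegsustain` implements a complete analysis chain for stratifying this
heterogeneity:

1. **Spectral features** — regional band power (delta 0.5–3.5, theta 4–8,
   beta 13–30 Hz; alpha 8–13 Hz is computed but not modelled) from Welch
   periodograms over eyes-closed EEG, averaged within eight cortical
   regions of interest.
2. **Harmonization** — control-referenced W-scores: each feature is
   regressed on age and sex over healthy-control (HC) baseline rows and
   expressed as a residual z-score, with per-feature sign inversion so
   disease-associated deviation is always positive.
3. **Subtype and Stage Inference (SuStaIn)** — a z-score event-based
   mixture model over orderings of biomarker threshold events, fitted by
   greedy ascent plus Metropolis MCMC, with the subtype count chosen by a
   cross-validation information criterion (CVIC).
4. **Longitudinal metrics** — subtype transition matrices, retention
   tests, per-year stage velocity with the `ΔStage ≥ 2`/year
   high-progression class.
5. **Outcomes** — Kaplan–Meier conversion-free survival by stratum,
   log-rank tests with FDR-adjusted pairwise comparisons, Fisher's exact
   test, and the logistic odds ratio of conversion per 5 stages.
6. **Synthetic cohorts** — a generator with the full statistical structure
   the model assumes, carrying ground truth for every recovery analysis.

## The progression model

Each of the `B` modelled biomarkers contributes two *events*: its
expected control-referenced z-score crossing `z1 = 1.5` and `z2 = 3`.
A *subtype* is an ordering `S` of all `E = 2B` events (within a
biomarker, the `z1` event must precede the `z2` event). A subject's
*stage* `k ∈ {0, …, E}` counts the events that have already occurred.

The expected z of biomarker `b` at stage `k`, `g_b(k)`, is the
piecewise-linear curve through `(0, 0)`, `(pos(z1), 1.5)`, `(pos(z2), 3)`
and `(E, z_max)`; `z_max = 5` is the configurable plateau (it only needs
to exceed `z2`; it is reported in the model metadata). Observation noise
is Gaussian with `σ_b = 1` by default — natural, since the inputs are
HC-standardized. The stage prior is uniform over `0..E` (the
maximum-entropy default of this model class), so

$$P(x \mid S) = \frac{1}{E+1} \sum_{k=0}^{E} \prod_b
  \mathcal N\!\left(x_b;\, g_b(k),\, \sigma_b^2\right),$$

computed with log-sum-exp stabilization. A `C`-subtype model mixes
sequences with fractions `f_c`.

**Fitting.** For `C = 1`: multi-start greedy ascent (default 25 random
restarts) repeatedly applies the single event relocation that most
improves the total log-likelihood, then a Metropolis chain (default
10,000 iterations; symmetric relocate-one-event proposals restricted to
valid orderings) refines the optimum and yields thinned samples for
positional-uncertainty displays. For `C > 1` the model grows
hierarchically: the weakest-fitting subtype's subjects are split and each
half's ordering fitted separately, followed by
expectation-maximization (soft responsibilities marginalized over
stages; M-step updates fractions and re-optimizes each ordering with
responsibility-weighted greedy + short MCMC, tolerance `1e-6`, at most
100 iterations). Two details matter in practice and are deliberate
design choices:

- *Split initialization.* Random halves of a mixed cohort fit
  near-identical "average" orderings, a symmetric fixed point that soft
  EM cannot leave. The first split therefore uses k-means on
  direction-normalized z-rows (pattern, not severity), further splits are
  random, and a few hard-assignment EM rounds precede the soft updates.
  The best of `split_tries` runs is kept.
- *Flat-likelihood detection.* When every subject MAP-stages at 0 the
  ordering is unidentifiable; the fit warns rather than pretending the
  returned permutation is meaningful.

**Placement.** The joint posterior
`P(c, k | x) ∝ f_c (E+1)^{-1} Π_b N(x_b; g_b(k), σ_b²)` is maximized,
ties broken toward smaller stage then smaller subtype. Subjects whose
MAP stage is 0 are labelled **subtype 0** — the group without
distinguishable spectral abnormality (all features below the first
threshold). MAP-stage-0 labelling is the default; the stricter hard
pre-filter (force stage 0 whenever every `|z| < 1.5`) is available as
`hard_zero = TRUE`, since either reading of the published convention is
defensible.

**Model selection.** Subject-level 5-fold cross-validation (80/20
splits): `CVIC(C) = −2 ×` summed held-out log-likelihood. The chosen `C`
is the smallest candidate no larger candidate beats by more than
`ε = 6` — an explicit, configurable version of the qualitative
"most parsimonious balance" rule.

## Harmonization choices

- The W-score regression is linear in age with an additive binary sex
  term and no interaction — the minimal convention. Residual SD uses
  denominator `n − 3`, so re-applying the fit to its own controls gives
  per-feature mean 0 and (residual-convention) SD exactly 1.
- Sign inversion is decided **per feature** from the pooled baseline
  disease mean (converters and non-converters together, so the rule never
  peeks at outcomes): negative mean ⇒ flip. An exact zero keeps the
  identity orientation, for determinism. The per-feature rule is the most
  granular reading of "regional power values were sign-inverted".
- Follow-up visits are scored with the frozen baseline-fitted parameters
  and flags; nothing is re-estimated at follow-up.
- Alpha power is excluded from the model (dimensionality reduction to
  delta/theta/beta × 8 regions = 24 features) but kept in the feature
  table for spectral comparisons.
- Inversion flags live in the parameter object, never in the data, so a
  double application is detectable and refused.

## Spectral front end

Welch's averaged periodogram with 2-s Hamming windows and 50% overlap
(2 s resolves the 0.5 Hz delta edge; ~100 averages from a typical
100-s eyes-closed recording), mean-removed segments, one-sided density
scaling, trapezoid integration over bins whose centers fall inside the
band. Windows never span an eyes-closed concatenation boundary, which
avoids discontinuity artifacts. Filters are zero-phase: 4th-order
Butterworth high-pass at 0.5 Hz plus an RBJ biquad notch (Q = 30) at the
power-line frequency, both applied forward–backward and recorded in the
recording's provenance. Artifact rejection is out of scope; the pipeline
assumes pre-cleaned signals and records a `cleaning_assumed` flag.

The default channel→region map (58-channel 10–10 montage onto eight
regions) ships as a TSV and is always an explicit, auditable input. The
medial/lateral frontal–central–parietal + occipital + temporal scheme
follows the naming used in the results of the source cohort; the methods
section of that work lists a slightly different eight-region scheme
(e.g. a temporal basal region) — the discrepancy is surfaced here rather
than silently resolved, and any mapping can be supplied.

## The synthetic generator

`sim_config()` fixes the study conditions: 51 controls and 234 disease
subjects by default; two latent subtypes (a posterior-beta-early
phenotype and a frontal-theta → frontal/temporal-delta phenotype,
mixed 51:64 among staged subjects); a truncated-geometric baseline stage
distribution with parameter 0.5 so roughly half the disease cohort sits
at stage 0; unit observation noise; raw features generated through a
per-feature affine age/sex model with beta-band features given negative
disease direction (so inversion is exercised); follow-up intervals of
3.8 ± 1.5 years; stage advancement `Poisson(λ_c Δt)` with
`λ = (0.1, 0.9)` stages/year (a static and a progressive subtype);
generating-subtype shifts with probability 0.1; and a piecewise-constant
yearly conversion hazard `h(t) = h0 · exp(ln(OR)/5 · stage(t))` with
`h0 = 0.02`, OR per 5 stages 2.14, censoring at 7.5 years. Every table is
byte-reproducible from `(config, seed)`.

Default true orderings are *staircases* (each biomarker passes `z1` then
`z2` before the next biomarker starts, in a subtype-specific biomarker
order): valid by construction and maximally distinct between subtypes,
mirroring the saturated-early-events character of the published
phenotypes.

What the generator does **not** emulate: EEG artifacts, volume
conduction, non-Gaussian feature noise, site effects, nonlinear age
trends, or competing risks across conversion phenotypes. Passing
recovery tests therefore demonstrates internal consistency of the
pipeline under its own assumptions, not robustness to real-world
violations of them.

## Recovery experiments and problem sizes

The packaged experiments (tests and `scripts/acceptance.R`) use sizes
chosen as realistic desk-scale studies:

- *Oracle equivalence*: 3 biomarkers (6 events, 90 valid orderings,
  exhaustively enumerable), n = 200, 20 seeded replicates.
- *Two-subtype recovery*: 12 biomarkers (24 events), n = 400, σ = 1,
  staircase truths, near-uniform baseline stages (`stage_rho = 0.05`) —
  recovery metrics over the stage axis need occupancy across it, unlike
  the half-at-zero cohort default. Subtype accuracy is evaluated among
  subjects with true stage > 0, where a subtype is defined.
- *Subtype-count selection*: 6 biomarkers, n = 300, candidates {1, 2},
  five replicates per truth.
- *Hazard recovery*: replicate-averaged logistic fit over 10 cohorts of
  n = 1000 with a 9-biomarker stage axis and `h0 = 0.0015`. The logistic
  odds ratio on cumulative conversion equals the hazard's odds ratio
  only where event probabilities are small (the log-odds of
  `1 − exp(−Λ)` is linear in stage with slope `ln(OR)/5` in that limit),
  so this experiment deliberately sits in the rare-event regime; the
  residual upward bias of the logistic estimand relative to the hazard
  parameter is a property of the estimand pair, not an estimation error.

Fitting budgets in the packaged experiments (8 greedy restarts, a few
hundred MCMC iterations, 2 split tries) are reduced from the defaults
(25 restarts, 10,000 iterations); they reproducibly reach the
enumeration optimum at these sizes.

## A worked example

```{r example, eval = FALSE}
study <- simulate_study(sim_config(seed = 17))

pars <- fit_harmonization(study$features)
z <- harmonize_features(study$features, pars)
zd <- z |> dplyr::filter(group != "HC")

cv <- select_subtypes(zd, c_max = 3, seed = 17,
                      control = sustain_control(n_starts = 8,
                                                mcmc_iter = 500))
model <- sustain_fit(zd, C = cv$chosen, seed = 17)
placement <- sustain_place(zd, model)

z_fu <- harmonize_features(study$features_followup, pars)
pairs <- pair_visits(placement, sustain_place(z_fu, model))
subtype_transitions(pairs)
deltas <- stage_deltas(pairs)

records <- survival_records(study$survival, placement, deltas)
km_fit(records, "baseline_subtype")
logrank_test(records, "baseline_subtype")
```

## Numerical details and edge cases

- Degenerate paired tests (all stage deltas equal) report `p = 1` with a
  flag instead of `NaN`.
- The velocity class boundary is closed on the high side:
  `v = 2.0` stages/year is "high".
- Fisher's exact two-sided p uses the point-probability rule (sum of all
  table probabilities not exceeding the observed one, with `1e-12`
  slack) — the convention that reproduces the published worked example
  and matches `stats::fisher.test`; tail-doubling is available as an
  option.
- The one-sample retention chi-square requires its null proportion
  explicitly: the published test's null is not recoverable from the
  reported statistic, so no default is supplied.
- Complete separation in the stage–outcome logistic is detected and
  flagged; no finite odds ratio is reported.
- Multiple follow-ups use the earliest by default.
- Survival time is measured from the baseline EEG visit.
- EDF export scales each channel into the signed 16-bit range; the
  round-trip error is bounded by the digitization step.

## Known limitations

- The subtype-growth EM is a local optimizer; with weakly separated
  orderings it can return an averaged sequence (mitigated, not
  eliminated, by the k-means/hard-EM initialization).
- Subjects' progression speed is not modelled (no subject-specific rate
  term), matching the discrete-stage model class.
- Harmonization assumes linear age effects and a single site.
- The end-to-end "noise-free" identifiability holds up to the sampling
  error of the finite control sample used to fit the harmonization.
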