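# eegsustain

Subtype and Stage Inference for resting-state EEG progression in
prodromal synucleinopathy.

Isolated REM sleep behavior disorder (iRBD) carries a high risk of
phenoconversion to Parkinson's disease, dementia with Lewy bodies, or
multiple system atrophy — but individual trajectories diverge widely.
`eegsustain` stratifies that heterogeneity from quantitative EEG: it
turns multichannel resting-state recordings into regional spectral
band-power features, harmonizes them into control-referenced z-scores,
fits a z-score **event-based subtype-and-stage model** (SuStaIn) over
them, tracks subtype transitions and stage velocity across visits, and
stratifies conversion-free survival.

## The model

Each modelled biomarker $b$ (delta/theta/beta power in 8 cortical
regions, 24 features) defines two *events*: its expected
control-referenced z-score crossing $z_1 = 1.5$ and $z_2 = 3$. A
*subtype* is an ordering $S$ of all $E = 2B$ events; a subject's *stage*
$k$ counts events already occurred. Expected trajectories $g_b(k)$ are
piecewise linear through $(0,0)$, $(\mathrm{pos}(z_1), 1.5)$,
$(\mathrm{pos}(z_2), 3)$, $(E, z_{\max})$, and the subject likelihood
marginalizes a uniform stage prior:

$$P(x \mid S) = \frac{1}{E+1}\sum_{k=0}^{E}\prod_b
\mathcal N\!\big(x_b;\, g_b(k),\, \sigma_b^2\big).$$

A $C$-subtype model mixes orderings with fractions $f_c$, fitted by
multi-start greedy ascent + Metropolis MCMC over orderings and
expectation-maximization for $C > 1$; the subtype count is chosen by a
cross-validation information criterion (CVIC = −2 × held-out
log-likelihood). Subjects whose MAP stage is 0 form **Subtype 0** (no
feature beyond the first threshold). Velocity
$\Delta\mathrm{Stage}/\Delta t \ge 2$ stages/year defines the
high-progression class.

## Worked example

A fully synthetic study (51 controls, 234 patients, two latent subtypes,
follow-up EEG and conversion outcomes; a compact four-region feature set
keeps the fit around two minutes):

```r
library(eegsustain)
library(dplyr)

study <- simulate_study(sim_config(
  seed = 17, rois = c("mfrontal", "lfrontal", "occipital", "temporal")))

pars <- fit_harmonization(study$features)
glance(pars)
#>   n_features  n_hc n_inverted
#> 1         12    51          4

z  <- harmonize_features(study$features, pars)
zd <- filter(z, group != "HC")
model <- sustain_fit(zd, C = 2, seed = 17,
                     control = sustain_control(n_starts = 4,
                                               mcmc_iter = 300))
glance(model)
#>       C n_events n_subjects loglik converged flat_likelihood
#> 1     2       24        234 -4782.  TRUE     FALSE

placement <- sustain_place(zd, model)
count(placement, subtype)
#>   subtype     n
#> 1       0    96
#> 2       1    34
#> 3       2   104
```

All four inverted features are beta-band (the generator gives beta a
negative disease direction, exactly the situation sign inversion
exists for). 96 of 234 patients sit at stage 0 — the sub-threshold
Subtype 0 group.

Longitudinal placement and outcome stratification:

```r
z_fu  <- harmonize_features(study$features_followup, pars)
pairs <- pair_visits(placement, sustain_place(z_fu, model))
subtype_transitions(pairs)   # baseline x follow-up counts and row %

records <- survival_records(study$survival, placement,
                            stage_deltas(pairs))
glance(logrank_test(records, "baseline_subtype"))
#>   statistic    df p.value
#> 1      11.6     2 0.00299
```

The global log-rank (χ² = 11.6, 2 df, p = 0.003) says conversion-free
survival differs across the three baseline subtype strata of this
synthetic cohort. `autoplot()` methods draw the positional-variance
diagram of a fitted model and Kaplan–Meier curves;
`plot_transitions()` draws the transition matrix.

The printed worked example from the source cohort's figures is a
one-liner:

```r
fisher_exact(matrix(c(51, 0, 45, 19), 2, byrow = TRUE))$p.value
#> [1] 4.352536e-06
```

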