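---
title: "Quantifying the legacy effect of synthetic N fertiliser from long-term experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the legacy effect of synthetic N fertiliser from long-term experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlegacy)
```

## The problem

Fertiliser recommendation systems are built almost entirely on first-season
nitrogen recovery: the fraction of this year's applied N that this year's
crop takes up. But synthetic fertiliser N that is *not* recovered in the
season of application is not all lost — a substantial part is retained in
the soil organic pool and remineralised in later seasons, where a crop can
still capture it. Long-term experiments (LTEs), which maintain fixed
fertilised and never-fertilised plots on the same land for decades, are the
only setting in which this *legacy effect* can be observed directly.

`nlegacy` implements the complete analysis chain for such data:

1. **Recovery statistics** per site-year,
2. a **weighted linear mixed-effects meta-model** across experiments,
3. **exhaustive AICc model selection** over agronomic and climatic
   co-variables, and
4. a **synthetic LTE generator** whose generative process embodies the
   multi-year retention/remineralisation mechanism, so every stage of the
   pipeline can be validated against known truth.

## Recovery statistics

All statistics are defined on aboveground crop N uptake (kg N/ha) and
expressed as fractions of the annual N rate. Internally everything is a
fraction; percentages appear only in reports.

**Long-term apparent recovery** compares the long-term fertilised plot with
the never-fertilised control in the same year:

$$RE^{LT} = \frac{U^{N,LT} - U^{0N,LT}}{N_{rate}}.$$

It includes capture of previously applied fertiliser N remineralised from
the soil, so $RE^{LT} > 1$ is legal (and occurs in real data); such records
are retained and flagged, never dropped.

**First-season recovery** comes from one of two superimposed short-term
treatments inside the long-term fertilised plot:

* *Subplot method* — withhold N for one season on a subplot:
  $RE^{1st} = (U^{N,LT} - U^{0N,ST}) / N_{rate}$;
* *$^{15}$N method* — label one season's fertiliser:
  $RE^{1st} = U^{15N} / {}^{15}N_{rate}$.

**The legacy effect** is their difference, $\Delta RE = RE^{LT} - RE^{1st}$,
both parts measured in the *same* year so that annual weather variation
cancels. For the subplot method the algebra collapses to a form that needs
no fertilised-plot measurement at all,
$\Delta RE = (U^{0N,ST} - U^{0N,LT}) / N_{rate}$, and the package verifies
the two routes agree to machine precision. A worked case: 29 kg N/ha of
extra uptake in a withheld season on a plot historically given 192 kg
N/ha/yr gives $\Delta RE = 29/192 = 15.1\%$.

`build_recovery_table()` assembles one analysis record per (site, year,
method); a site-year offering both subplot types yields **two** records
sharing $RE^{LT}$. Each record carries the replicate weight
$w = n_{\text{years pooled}} \times n_{\text{field reps}}$. Experiments
whose design only permits a direct $\Delta RE$ estimate enter through a
`direct_delta` pass-through with a weight but no recovery parts; no
functional form is assumed for how such values were derived externally.

One subtlety of the co-variable join: `duration_years` in the covariate
file describes the site's *first* sampling year, and records sampled in
later years of the same experiment are aged accordingly. This matters —
with nine experiments, a model with many purely site-level predictors is
not identifiable; within-site variation in duration (and, where real, in
crop) is what the actual compilations provide.

## The meta-model

Records are aggregated with the weighted linear mixed model

$$y_{i} = \mathbf{x}_i^\top \beta + u_{site(i)} + v_{year(i)} +
\varepsilon_i, \qquad
u \sim N(0, \sigma^2_s), \quad v \sim N(0, \sigma^2_y), \quad
\varepsilon_i \sim N(0, \sigma^2 / w_i),$$

with *crossed* (not nested) random intercepts: experiment location and
calendar year each get their own intercept, since the same year's weather
anomaly can touch several experiments. Weights enter as inverse-variance
multipliers on the residual; the estimate is invariant to rescaling all
weights by a constant, so they need no normalisation.

The implementation profiles the likelihood: for variance ratios
$\gamma = (\sigma^2_s, \sigma^2_y)/\sigma^2$ and
$V(\gamma) = \gamma_s Z_s Z_s^\top + \gamma_y Z_y Z_y^\top + W^{-1}$, the
GLS solution $\hat\beta = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$ and a
closed form for $\hat\sigma^2$ reduce estimation to a two-dimensional
search over $\gamma \ge 0$. That search is a coarse grid (including the
$\gamma = 0$ boundary) followed by Nelder-Mead on $\sqrt\gamma$ with
relative tolerance $10^{-10}$; parameterising by the square root makes the
boundary reachable without constraints. Gamma values where $V$ or
$X^\top V^{-1}X$ is numerically singular score $-\infty$ and are simply
avoided. At $\gamma = (0,0)$ the whole stack collapses to weighted least
squares, which the tests verify against `lm(..., weights = )` to $10^{-8}$;
on realistic data the fit agrees with `lme4::lmer` (an independent
implementation, used in the test suite only as a cross-check) in
coefficients, variance components and REML log-likelihood.

### Conventions that the data do not dictate

Several choices are under-determined by the problem and are therefore made
explicitly, logged by every pipeline run, and held fixed:

* **ML for comparison, REML for reporting.** REML criteria are not
  comparable across fixed-effect sets, so all-subsets selection fits by ML;
  reported estimates and intervals come from REML refits.
* **AICc parameter count** $k$ = fixed effects (including intercept) + 2
  random-intercept variances + 1 residual variance, with
  $AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$.
* **Confidence intervals** are Wald-*t* with $df = n_{obs} - n_{sites}$ —
  deliberately simple and stated, rather than an unstated package default.
  No Satterthwaite or Kenward-Roger correction is attempted.
* **Standardisation** of continuous co-variables is unweighted z-scoring;
  categorical co-variables are one-hot encoded against the alphabetically
  first level; binary indicators stay 0/1.
* **Ties** in AICc are broken by fewer parameters, then by the
  lexicographic term set, making the ranking deterministic and independent
  of record order.
* The optional **outlier rule** in the paired method contrast (drop the
  single record with $|$studentised residual$| > 3$, at most once) is OFF
  by default and announces itself when used.

`dredge_aicc()` enumerates all $2^9 = 512$ subsets of the nine candidate
terms (growing degree days, temperature seasonality, aridity index, crop
type, experiment duration, average N rate, clay content, first-season
method, residue retention); models within 2 AICc units of the best form
the selected set. `mean_delta_re()` reports both the mixed-model intercept
and the plain weighted mean, because with unbalanced designs the two
differ and it is ambiguous which convention an external report used.

## Climate co-variables

Three climate-zone descriptors are computed from daily weather:
growing degree days $\sum_d \max(T_d - T_{base}, 0)$, the aridity index
(annual precipitation over annual potential evapotranspiration; PET is an
input, no evapotranspiration model is included), and temperature
seasonality (sample SD, divisor 11, of the twelve monthly means). The base
temperature defaults to 0 °C — the common small-grain convention — and the
divisor choice is recorded here precisely because neither is dictated by
the data; both are configuration. Multi-year series are handled by
computing each index per calendar year and averaging.

## The synthetic generator

The generator is not a mechanistic soil model; it is a statistical test-bed
whose *expected values* follow the mechanism the analysis is meant to
detect. Each season a site receives `n_rate` kg N/ha: a fraction `r1`
(default 0.45) is recovered by the crop that season, `rho` (default 0.30)
is retained in the soil, and the remainder is lost (the loss pathway split
is deliberately not modelled). Retained cohorts remineralise by age —
10% of the *applied* amount in the second season (capped at the pool), 3%
of the *remaining pool* in the third, 1% of the pool in each later season —
and remineralised N is captured with efficiency `e_min` (default `r1`;
the data say nothing about how efficiently remineralised N is captured, so
it defaults to the fertiliser value). The mixed-base schedule is
implemented literally, with the cap preserving cohort N conservation:
cumulative release never exceeds `rho * n_rate` per cohort.

`expected_delta_re(cfg, t)` is then the exact noise-free legacy effect:
zero at $t = 1$, monotone in $t$, asymptoting to `e_min * rho` as every
pool eventually empties. At the default 16-season horizon it is
$\approx 0.058$ — the generator's truth for a *single* pulse-chain of this
kind, against which the pipeline is checked exactly (noise off) and in
Monte-Carlo mean (noise on). Native soil N supply declines exponentially
from `s0 = 60` to a floor `s_min = 35` kg N/ha — unfertilised-control
uptakes in the 35–60 kg N/ha range are typical of old temperate LTE
controls — which matters only through the control-plot uptake level.

### The study-like compilation

`make_study_like_dataset()` emulates a nine-experiment compilation with 66
analysis records: site-level crops (winter wheat, maize, spring and winter
barley), durations 5–140 years, N rates 34–269 kg N/ha/yr, clay 15–28%,
residues retained at three sites, and three experiments offering both
first-season methods (16 paired records). Record-level legacy effects are
drawn as $0.244 + u_{site} + v_{year} + e$, with site SD 0.10, year SD
0.05 and record SD $0.08/\sqrt{w}$. The effect-scale SDs were chosen so
that a 66-record analysis yields a 95% CI half-width of roughly 8–12
percentage points, the scale reported for compilations of this size; the
designed truth 0.244 is what the parameter-recovery tests (bias of the
mean estimate, CI coverage) are scored against. First-season recoveries
scatter around site bases averaging ≈ 0.43, so long-term recoveries land
around 0.68.

What the fixture does *not* emulate — and hence what passing tests do not
establish about real data: digitisation error and reporting heterogeneity
across source articles; added-nitrogen interactions beyond a single
proportional bias knob (`delta15_bias`); priming; residue-return N flows
(residue retention is a label only); correlated co-variables (the fixture's
co-variables are fixed design values, so collinearity diagnostics on it are
unexciting by construction); and any trend of $\Delta RE$ with duration,
which the generator deliberately leaves flat at the fixture's horizons.

## Problem sizes and runtime choices

The test suite and the acceptance script were sized to run comfortably on a
single core: parameter-recovery uses 200 replicate datasets of 66 records;
the generator-bias checks use 500 single-site replicates; the full 512-model
dredge runs once per invocation (a few seconds per 512 fits at $n = 66$);
the selection-consistency property is exercised on a 4-term (16-model)
candidate set over 40 replicates, which tests the same mechanics as the
full set at a fraction of the cost. The acceptance script averages its
stochastic quantities over 10 replicate datasets.

## Degenerate inputs and numerical edges

* Datasets with a single year or a single site are legal where the
  requested quantity remains estimable (incidence matrices are built
  directly, so one-level grouping factors work); estimating a site variance
  from one site is refused.
* A continuous co-variable with zero variance cannot be z-scored; the
  standardiser refuses it *by name*. The pipeline driver catches this, logs
  it, and skips selection/diagnostics rather than failing the run.
* Weighted uptake values are written to CSV at 6 significant digits; the
  writer is byte-deterministic, and reading back a written dataset is the
  identity because the study-like generator emits uptakes already at that
  resolution.
* Labelled uptake above the labelled rate is *not* rejected (measurement
  noise can produce it); negative uptakes are.

## A short session

```{r example, eval = FALSE}
ds <- make_study_like_dataset(seed = 1)
tab <- build_recovery_table(ds)
mean_delta_re(tab)
method_contrast(tab)
std <- standardise_covariates(tab)
dredge_aicc(std)
```

## Known limitations

The package analyses compiled plot-level means; it cannot reconstruct
within-plot variance that source articles did not report, which is exactly
why replicate counts act as weights. The `direct_delta` route accepts
externally computed legacy effects at face value. The mixed model assumes
Gaussian effects and residuals; the diagnostics report skewness and excess
kurtosis of the response rather than pretending to test normality at
$n = 66$. And the generator's remineralisation schedule is one defensible
literal reading of a mixed-base description ("of the applied amount" vs
"of the remainder"); all three rates are configurable precisely because
that reading is a choice.
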