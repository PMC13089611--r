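---
title: "Methods: from ring widths to mixture-by-drought effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from ring widths to mixture-by-drought effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(droughtmix)
```

This vignette documents the scientific and numerical choices behind the
package: what each stage computes, which parameters matter and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the limitations a user should keep in mind.

## Growth processing

**Basal-area increment.** Ring widths (mm, 0.01 mm precision) become annual
basal-area increments `bai_t = π(r_t² − r_{t−1}²)` (cm²). The default radius
anchor is *outside-in*: the final radius is pinned at `dbh/2` and earlier
radii are reconstructed by subtracting widths. This respects the measured
tree size; no bark correction is subtracted because bark thickness is not
among the inputs. An *inside-out* mode (accumulate from the pith) is
available; it is exact for complete-to-pith series and satisfies the
telescoping identity `Σ bai = π r_final²`. Each core is converted
separately and the per-tree BAI series is the mean of its cores; averaging
at the BAI stage (rather than averaging widths first) is the default
because the response variable of the study is area increment.
Width-level averaging is available through `merge_cores()`.

**Detrending.** Age- and size-related trends are removed by dividing by a
cubic smoothing spline. The smoother is a second-difference penalized
(Whittaker–Henderson) fit — the discrete form of the cubic smoothing
spline — whose frequency response is `H(f) = 1/(1 + λ(2 sin πf)⁴)`.
Setting `λ = (2 sin(π/L))⁻⁴` puts 50% amplitude exactly at wavelength
`L` (default 30 years). The implementation is verified spectrally: a
300-year sinusoid of period 30 years is attenuated to 0.50 of its input
amplitude (FFT oracle), a constant is reproduced exactly, and ratio
indices average to 1 within ±0.05 on realistic series. Detrending is by
division ("ratio indices"), the standard choice for dimensionless growth
indices; fitted values are clamped strictly positive before division and a
fit that collapses to the clamp floor raises an error rather than
returning indices.

**Chronologies and signal statistics.** The site chronology is Tukey's
biweight robust mean (tuning constant c = 9, median-absolute-deviation
scale, iterated to convergence) of all indices available in a year; with
fewer than four series the arithmetic mean is used, and a zero MAD returns
the median. rbar is the mean Pearson correlation over all series pairs
with at least 20 overlapping years (configurable), glk the mean proportion
of same-sign year-to-year changes (a zero change scores ½ against a
non-zero one, via `1 − |s₁ − s₂|/2` on sign triples), and
`eps = n·rbar/(n·rbar + 1 − rbar)`. These statistics are computed on the
detrended indices over each pair's common overlap; the convention is
exposed as configuration because reported chronologies do not always state
it.

## Climate indices

Monthly potential evapotranspiration uses the Hargreaves equation,
`PET = 0.0023 · Ra · (T̄ + 17.8) · √(Tmax − Tmin)` per day times days in
month, floored at zero; `Ra` is FAO-56 extraterrestrial radiation at the
mid-month day (validated against the published FAO-56 worked value for
20°S, early September, within 2%). The climatic water balance is
`D = P − PET` per month.

SPEI integrates `D` over a window of `k` months ending in a fixed calendar
month (a 12-month window ending in July reaches back to the previous
August), fits a three-parameter log-logistic distribution to the
reference-period sums by unbiased probability-weighted moments, and maps
each sum through the fitted CDF and the Abramowitz–Stegun rational
approximation of the standard-normal quantile. One fit serves the whole
annual series; the reference period defaults to the full record and is
configurable.

Two numerical choices deserve note. First, the log-logistic carries its
heavy tail on the right and a finite bound on the left; a sample whose
skew points the other way (deep deficit years pull the third L-moment
negative) cannot be fitted in the standard orientation, so the package
fits the *reflected* log-logistic in that case (`method`
`"loglogistic-reflected"` on the result). If the PWM fit is invalid either
way (shape ≤ 1, or the location bound inside the data), the series falls
back to Gringorten plotting-position standardization, flagged
`"empirical"`. Second, because the index is calibrated to standard-normal
units on its reference period, about 2.3% of reference years will fall
below −2 *by construction*; "extreme drought" flags are statements about
relative rank, and on a 40-odd-year record the sample minimum lands near
−2.2 whether or not anything unusual happened. Threshold crossings should
therefore be read jointly with the underlying water-balance sums.

## Competition and admixture

The Hegyi competition index sums `(dbh_j/dbh_i)/dist_ij` over living
neighbours with dbh ≥ 1 cm within 7 m. Dead stems are recorded and
reported as deadwood basal area but never compete. Admixture is the
interspecific share of CI in percent; the three-category gradient
(<25%, 25–75%, >75%) assigns the boundary values to the middle category,
keeping the extreme categories open and the middle one closed. Biogroup
basal area scales by the exact circle area `π·7² = 153.94 m²` rather than
the rounded 154 (a 0.04% difference, but reproducible).

## Drought responses and species comparisons

The response of tree *i* to drought *j* is
`100 · rwi_ij / mean(rwi over the 2 preceding years)`. Two years is long
enough to smooth one anomalous pre-year yet short enough to stay clear of
the previous drought (growth autocorrelation at 1–2 year lags is strong,
≈ 0.6 in the generator default). A tree whose pre-window is incomplete is
dropped with a log message — shortening the window silently would change
the statistic's definition mid-sample. When the pre-window of one event
would overlap another configured event, extraction errors out rather than
guessing.

Species are compared within region × drought event by two-sided Wilcoxon
rank-sum tests: the exact null distribution when the combined sample is
≤ 20 and tie-free, the tie-corrected normal approximation with continuity
correction otherwise, Bonferroni-multiplied per group, with compact
letters at p ≤ 0.001. The exact branch is validated against exhaustive
permutation enumeration for all group sizes up to 7.

## The hierarchical model

Relative growth change is modelled on the response-ratio scale
(y = 1 means no change) with a log-normal observation model and no overall
intercept:

```
ln y_i ~ Normal(μ_i, σ)
μ_i = β_CI·CI_i + β_mix·mix_i + β_dbh·dbh_i
      + β_first·I(first)_i + β_second·I(second)_i
      + β_mix:second·mix_i·I(second)_i
      + σ_α·α_tree(i) + σ_γ·γ_site(i)
```

CI, admixture and dbh are standardized within each species × region
dataset (both drought rows pooled), so effects are per-SD and comparable
across predictors; the drought indicators replace the intercept, and the
interaction is expressed against the first drought as reference slope.
The ratio scale matters: with weakly informative normal(0, 1) priors and
no intercept, the drought-level coefficients sit near `ln 0.75 ≈ −0.3`,
inside the prior's plausible range, whereas a percent-scale response would
force them to ≈ 4.3 and make the prior actively misleading. Priors are
normal(0, 1) on all coefficients and half-normal(0, 1) on σ, σ_α and σ_γ —
the conventional weakly informative analogue for scales, which must be
chosen because positivity rules out a plain normal. Tree and site effects
are non-centred (standard-normal effects scaled inside μ).

**Sampler.** On the log scale the model is linear-Gaussian, and the
sampler exploits that: all location parameters (β, α, γ) are drawn jointly
from their exact multivariate-normal full conditional (one Cholesky per
iteration), which removes the slow ridge between drought-level
coefficients and site effects that coordinate-wise updates suffer from;
the effect scales get truncated-normal conjugate draws followed by an
ancillarity–sufficiency interweaving step (re-expressing the effects in
centred form and slice-sampling the scale) to avoid the funnel; σ is
slice-sampled on the log scale. Every update targets the exact posterior —
no approximation error beyond Monte Carlo — and runs are bit-reproducible
for a fixed seed. The default configuration is 4 chains × 6000 iterations
with 2000 warmup (4000 retained per chain), read as total iterations; the
20-replicate recovery study in the tests runs 3000/1000 per chain, which
this sampler's per-iteration efficiency makes more than sufficient (the
full study sits near 3 minutes on one CPU).

**Diagnostics.** Split-chain Gelman–Rubin R̂ per parameter (halved chains,
so within-chain drift inflates the statistic); posterior predictive
replicates of the full response vector with tail probabilities for mean,
SD and decile statistics; Bayesian R² per draw as
`var(μ)/(var(μ) + σ²)` on the log scale (a response-scale variant uses the
log-normal mean/variance identities — the scale is a genuine choice and
both are provided); and PSIS influence diagnostics: per observation, the
generalized Pareto shape k̂ fitted (empirical-Bayes profile estimator with
the usual n/(n + 10) shrinkage toward 0.5) to the top `min(20%, 3√S)`
leave-one-out importance ratios, flagging k̂ > 0.7. In hierarchical models
with one or two observations per group, moderately large k̂ is expected
for unremarkable observations — each observation informs its own tree
effect — so flags are a prompt for inspection; refitting without a flagged
observation is an explicit user action, never automatic.

## The synthetic-data generator

The generator exists so the pipeline and the model can be tested end to
end with a recorded truth. It emulates: a two-species stand with one
clumped species (Thomas cluster process; parent intensity 12 ha⁻¹,
offspring dispersion 4 m) and one dispersed species (homogeneous Poisson),
log-normal dbh; target selection stratified to 10 trees per admixture
category per species (realized CI-based admixture, whole-stand retry if a
quota fails); monthly climate with sinusoidal temperature normals and
right-skewed gamma(4, 18) precipitation (mean 72 mm), with drought years
forced by suppressing March–August precipitation to 35% and widening the
diurnal range by 3 °C — strong enough that the SPEI stage flags exactly
those years; and per-tree growth indices: a stationary AR(1) baseline
around 1 (lag-1 0.6, marginal SD 0.15, half the variance shared within a
site so chronologies show realistic rbar/glk), with each drought-year
index overwritten as (response ratio) × (pre-drought mean), the ratio
drawn from the hierarchical model above. Default truth:
β_CI = −0.05, β_mix = 0.10, β_dbh = −0.05, β_first = −0.29 (≈ 75%
response), β_second = −0.51 (≈ 60%), β_mix:second = 0.30, σ = 0.30,
σ_α = 0.15, σ_γ = 0.20 — sample sizes and design (2 sites × 2 species ×
30 trees, 10 per category) mirror the study layout, effect sizes are
modest and positive for the mixture interaction.

What it does **not** emulate: a mechanistic climate→growth link (drought
timing enters growth as a categorical event, matching how the inference
treats it, so climate and growth are linked only through the configured
drought list); missing rings, false rings or dating error; bark, height or
crown structure; edge effects at plot boundaries; measurement error beyond
3% multiplicative core noise. Passing tests therefore demonstrate that the
*machinery* is correct under the stated generative assumptions, not that
the substantive field conclusions transfer.

## Known limitations

* The RWL reader treats 999/−9999 as end sentinels; a genuine 0.999 mm
  ring in a 0.001-mm-unit file would be misread (the writer emits 0.01-mm
  units, where no ambiguity exists). Widths ≥ 9.99 mm are not
  representable in the written format.
* One log-logistic fit per window series (annual resolution); monthly SPEI
  surfaces are out of scope.
* With only two sites, σ_γ is prior-dominated; its posterior mostly
  reflects the half-normal(0, 1) prior, and Bayesian R² on such designs is
  shrunk relative to the realized variance ratio. The recovery study
  accounts for this by checking coverage, not point agreement.
* PSIS k̂ needs a few hundred draws per observation to stabilize; with
  heavy thinning the flags become noisy.
* Wilcoxon p-values with ties at small n fall back to the corrected
  normal approximation (the exact-with-ties null would need full
  permutation enumeration, which the oracle tests perform but the
  implementation deliberately avoids).
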