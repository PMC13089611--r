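# droughtmix

Tools and a worked analysis for a question in mixed-forest dendroecology:
**does growing next to another species soften a tree's growth response to
recurrent drought?** The package implements the full chain from raw
increment-core measurements and monthly climate to posterior distributions
of mixture-by-drought effects, together with a synthetic stand/climate/growth
generator so that every stage — and the model-fitting machinery as a whole —
can be validated against a known ground truth without any field data.

## The analysis in brief

1. **Tree rings.** Dated ring widths (Tucson/RWL format) are converted to
   basal-area increments, `bai_t = π (r_t² − r_{t−1}²)`, anchored outside-in
   at the measured dbh. Per-tree series are detrended with a cubic smoothing
   spline whose frequency response passes 50% amplitude at a 30-year
   wavelength, giving dimensionless ring-width indices (rwi). Site
   chronologies use Tukey's biweight robust mean, summarized by rbar
   (mean inter-series correlation), Gleichläufigkeit (glk), and the
   expressed population signal `eps = n·rbar / (n·rbar + 1 − rbar)`.
2. **Climate.** Hargreaves potential evapotranspiration from monthly
   temperature extremes and FAO-56 extraterrestrial radiation; climatic
   water balance `D = P − PET`; the Standardized
   Precipitation–Evapotranspiration Index by fitting a three-parameter
   log-logistic distribution (unbiased probability-weighted moments) to the
   windowed sums of `D` (e.g. SPEI6, March–August). Years with SPEI < −2
   count as extreme drought.
3. **Competition.** From 7-m stem-mapped neighbourhoods, the Hegyi index
   `CI_i = Σ_j (dbh_j/dbh_i)/dist_ij` and the admixture percentage
   `100 · CI_interspecific / CI_overall`.
4. **Drought response.** Relative growth change
   `100 · rwi(drought year) / mean(rwi of the two preceding years)`,
   compared across species with exact Wilcoxon rank-sum tests and
   Bonferroni correction.
5. **Model.** A Bayesian hierarchical log-normal regression with no overall
   intercept,
   `y ~ lognormal(μ, σ)`,
   `μ = β_CI·CI + β_mix·mix + β_dbh·dbh + β_drought·drought +
   β_mix:drought·mix:drought + α_tree·σ_α + γ_site·σ_γ`,
   standardized predictors, normal(0, 1) coefficient priors, half-normal(0, 1)
   scale priors, trees nested in sites. Sampling uses a blocked Gibbs
   sampler (the model is linear-Gaussian on the log scale) with split-chain
   R-hat, posterior predictive checks, Bayesian R², and PSIS Pareto-k
   influence diagnostics (flag at k > 0.7).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (all outputs land in `results/`):

```sh
Rscript analysis/01_simulate.R    # stands, climate, cores with known truth
Rscript analysis/02_pipeline.R    # rwi, chronologies, SPEI, CI, responses
Rscript analysis/03_models.R      # hierarchical fits + species tests
Rscript analysis/04_recovery.R    # 20-replicate closed-loop validation
```

`02_pipeline.R` prints the chronology overview, e.g.:

```
  site species  n    period           bai rbar  glk  eps
 siteA     oak 30 1975-2023 14.91 ± 11.31 0.28 0.64 0.92
 siteA    pine 30 1975-2023 19.67 ± 10.81 0.24 0.64 0.91
 siteB     oak 30 1975-2023 17.25 ± 11.89 0.52 0.64 0.97
 siteB    pine 30 1975-2023 22.72 ± 10.96 0.54 0.67 0.97

SPEI drought years per site (SPEI6 < -2):
  siteA : 2018, 2022
  siteB : 2018, 2022
```

— 30 trees per chronology, their common signal (rbar, glk), and how well
the sample represents the stand (eps close to 1); the SPEI stage flags
exactly the two drought years the generator forced. `03_models.R` then
reports, per species, the standardized effect table (posterior mean, 66%
and 95% credible intervals). With the default generative truth
(`β_mix:second = 0.3`) the admixture-by-second-drought interaction comes
back at `0.36 (95% CI 0.26–0.46)` for oak and `0.32 (0.22–0.42)` for pine:
trees with more heterospecific competition lost less growth in the second
drought. `04_recovery.R` closes the loop: over 20 simulated replicates of
the two-site, 60-tree design, the 95% credible intervals covered the nine
generative parameters in 95.6% of parameter-replicate pairs, recovered the
planted interaction sign in 20/20 replicates, with worst split-chain
R-hat 1.006.

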