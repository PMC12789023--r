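# priceparts

Local arthropod biomass is declining in many grasslands, but a biomass
trend alone cannot say *why*: is function being lost because species
disappear, because particular (non-average) species disappear, or
because the species that remain become less abundant? `priceparts`
answers this with the ecological (CAFE) form of the Price equation,
partitioning the biomass difference between two community samples into
five additive components, and wraps the partition in the full analysis
design needed for noisy multi-year community data: allometric
length–mass biomass estimation, within-year replicate synthesis,
pairwise comparison schemes with intra-annual controls, and
resampling-based mixed-model inference. It is aimed at community
ecologists analysing standardized arthropod (or other multi-species)
time series along environmental gradients such as sown plant species
richness (PSR) or land-use intensity (LUI).

## The partition

For a baseline sample with per-species biomass contributions `z_i`
(total `T`, richness `s`, mean `z̄ = T/s`) and a comparison sample
(`z'`, `T'`, `s'`), sharing `s_c` species (set `C`):

    SRE_L = -(s - s_c) · z̄              species richness loss  (≤ 0)
    SIE_L = Σ_C z_i  - s_c · z̄          species identity loss
    SRE_G = (s' - s_c) · z̄'             species richness gain  (≥ 0)
    SIE_G = s_c · z̄' - Σ_C z'_i         species identity gain
    CDE   = Σ_C (z'_i - z_i)             abundance change of persisters

    SRE_L + SIE_L + SRE_G + SIE_G + CDE = T' - T   (exactly)

Richness terms price species turnover at the community average; identity
terms absorb the deviation when lost/gained species are non-average; and
with constant per-species body mass the CDE isolates abundance change.
Trends in each component over time spans of 0 (same-year replicate
controls) to several years are estimated from ensembles of linear
mixed-effects models over random comparison subsets that never reuse a
sampling event.

## Worked example

```r
library(priceparts)

baseline   <- c(A = 4, B = 2, C = 6)
comparison <- c(A = 3, B = 2, D = 1)
price_partition(baseline, comparison)[, c("sre_loss", "sie_loss",
  "sre_gain", "sie_gain", "cde", "delta_T")]
#>   sre_loss sie_loss sre_gain sie_gain cde delta_T
#> 1       -4       -2        2       -1  -1      -6
```

Losing species C (biomass 6) costs the baseline average `-4` as a
richness effect; the extra `-2` is its identity effect. Gaining D adds
the comparison average `+2` minus an identity deficit of `-1`; the
persisting species A and B lose `-1` through abundance. The five terms
sum to the observed change `-6` mg.

The same partition, run as a full synthetic study (24 plots on a PSR
gradient, 7 sampling years with imposed richness-dominated decline,
restricted-moving-average design, 100-model ensemble):

```r
set.seed(1)
cfg <- synthetic_config("experiment", n_plots = 24, n_species = 150)
sim <- simulate_observations(cfg)
fv  <- build_function_vectors(sim$observations, synthetic_allometry())
fvs <- function_vector_summary(fv)
pairs <- attach_covariates(
  enumerate_pairs(fvs, "restricted_moving_average"), sim$covariates)
part  <- partition_batch(pairs, fv)

set.seed(2)
ens <- ensemble_inference(part,
  responses = c("sre_loss", "sie_loss", "sre_gain", "sie_gain", "cde",
                "delta_T"),
  n_models = 100, cov_levels = c(1, 60))
component_contributions(ens, 7)
#>      group horizon    median     ci_low    ci_high n_models n_excluded
#> 1 richness       7 80.608649  49.287543 129.904064      100          0
#> 2 identity       7 -6.502191 -11.196773  -1.688143      100          0
#> 3 turnover       7 74.300810  43.604631 122.978710      100          0
#> 4      cde       7  8.550932   3.421726  15.215839      100          0

fy <- head(sort(unique(fvs$year)), 5)
percent_decline(ens, mean(fvs$T_mg[fvs$year %in% fy]), 7)[,
  c("yearly_pct", "yearly_ci_low", "yearly_ci_high")]
#>   yearly_pct yearly_ci_low yearly_ci_high
#> 1   7.241469      5.302753       8.927063
```

Read: at the 7-year horizon, ~74% (95% CI 44–123) of the predicted
biomass loss travels through species turnover — ~81% through richness
change alone, offset by a negative identity share — while abundance
declines of persisting species carry ~9%; total biomass declines ~7.2%
per year relative to the first-five-year baseline. Shares are ratios of
separately fitted models and need not sum to 100. (The printed ensemble
also reports VIFs of the fixed design; the covariate main effect and the
`span × covariate` interaction are intrinsically correlated because
spans are non-negative, and values ≥ 2 are flagged.)

## Repository layout

* `R/` — the package: data model and CSV I/O, biomass/function vectors,
  replicate synthesis, the Price partition, comparison designs and
  no-reuse subset sampling, ensemble inference, diagnostics, the
  synthetic-community generator with its Monte-Carlo oracle, and
  `run_pipeline()`.
* `analysis/01_simulate.R … 04_diagnostics.R` — the numbered analysis
  workflow over the package, writing tables under `results/`.
* `vignettes/price-partitioning.Rmd` — the methods account: model,
  assumptions, parameter choices, numerical conventions, limitations.
* `tests/testthat/` — unit, property and acceptance suites, including
  independent brute-force oracles for the partition and for maximum
  matchings.

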