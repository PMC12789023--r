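---
title: "Partitioning temporal biomass change into community (dis-)assembly components"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning temporal biomass change into community (dis-)assembly components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(priceparts)
```

## The question and the partition

When the total biomass of an arthropod community declines between two
points in time, the decline can come from losing species, from losing
*particular* (non-average) species, or from persisting species becoming
less abundant. `priceparts` separates these routes with the ecological
(CAFE) form of the Price equation, applied to pairs of community samples.

Write $z_i$ for the biomass contribution of species $i$ in a sample,
$T = \sum_i z_i$ for total biomass, $s$ for species richness and
$\bar z = T/s$. For a baseline sample $(z, s, T)$ and a comparison sample
$(z', s', T')$ sharing $s_c$ species (the set $C$), the five components
are

$$
\begin{aligned}
\mathrm{SRE}_L &= -(s - s_c)\,\bar z
  &&\text{species richness loss (} \le 0\text{)}\\
\mathrm{SIE}_L &= \textstyle\sum_{i \in C} z_i - s_c \bar z
  &&\text{species identity loss}\\
\mathrm{SRE}_G &= (s' - s_c)\,\bar z'
  &&\text{species richness gain (} \ge 0\text{)}\\
\mathrm{SIE}_G &= s_c \bar z' - \textstyle\sum_{i \in C} z'_i
  &&\text{species identity gain}\\
\mathrm{CDE} &= \textstyle\sum_{i \in C} (z'_i - z_i)
  &&\text{abundance change of persisters,}
\end{aligned}
$$

and they sum *exactly* to $\Delta T = T' - T$. The richness terms price
every lost (gained) species at its community's average; the identity
terms absorb the deviation when the species under turnover are
non-average; and because every species carries a constant literature
body length, per-species biomass can only change through abundance, so
the CDE isolates abundance change. A companion mode
(`mean_individual_biomass`) sets $z_i$ to the individual mass alone,
which removes abundance from the turnover terms and forces
$\mathrm{CDE} \equiv 0$ — a useful control for interpreting identity
effects.

```{r}
baseline <- c(A = 4, B = 2, C = 6)
comparison <- c(A = 3, B = 2, D = 1)
price_partition(baseline, comparison)[, 6:14]
```

Empty samples are legal: an empty side has no mean, its richness and
identity terms are zero, and all change loads on the other side's terms,
which keeps the sum identity exact. Two empty samples partition to zero.

## From field samples to function vectors

Observations arrive as one row per (plot, year, season, replicate,
species) count with a constant per-species body length. Individual dry
mass comes from taxon-specific allometric power laws $m = a L^b$ (mm to
mg); the packaged `allometry_synthetic.csv` is a synthetic placeholder
with one shared coefficient pair — analyses of real samples must supply
literature coefficients per taxon group. The two seasonal samplings of a
replicate are pooled before the partition; trophic-guild subsets
(herbivores, predators) are configuration variants that filter species
before pooling.

Designs without physical within-year replicates get them synthesized:
`split_sample()` draws a Poisson($N/2$)-sized subsample (truncated to
$[0, N]$) of individuals without replacement as replicate A and leaves
the complement as replicate B, conserving every species count exactly;
`bootstrap_replicate()` covers incomplete samplings by resampling a
Poisson($N$)-sized draw with replacement (the mean is configurable to
$N/2$; we default to $N$, a full-effort resample).

## The comparison design

Temporal trends are estimated from *pairwise* comparisons, not from raw
yearly values, because both series are strongly variable between years.
Three schemes are supported: a fixed baseline (everything against the
first year), a moving average (all ordered year pairs pooled by time
span), and the main restricted moving average (moving average whose
baselines lie among the first five sampled years). Spans realized by
fewer than two distinct year combinations are dropped — with sampling
years 2010, 2012, 2014, 2016, 2017, 2019, 2020 this retains a maximum
span of 7 years, and with annual 2008–2018 sampling 9 years. Same-year
replicate pairs (span 0) enter as controls: they quantify the turnover
expected from detection alone and anchor the regressions at year 0.
Within a plot, temporal pairs connect identical replicate labels; a
"first five years" window counts sampled years, not calendar years.

Because each sample takes part in many comparisons, using all pairs in
one model would pseudo-replicate. Instead the ensemble draws random
subsets in which every sampling event — one physical sample, i.e. a
(plot, year, replicate) — appears at most once; a control consumes both
replicate events of its plot and year. The subset size is pinned to the
per-plot maximum matching of the pair graph (computed exactly by
branch-and-bound; the sampler shuffles and greedily accepts, restarting
until it reaches that size), so every draw has identical, maximal size.
Control direction (A vs B or B vs A) is randomized per draw; reversing
a pair negates `delta_T` and `CDE` and exchanges loss with gain terms
under a sign flip, which the implementation applies algebraically.

## Inference over the ensemble

Each response (the five components, total change, species lost, gained,
net) is square-root transformed on its absolute value with the sign
restored — biomass change is sign-symmetric with heavy tails, and the
signed root is odd, strictly increasing and exactly invertible. On each
of `n_models` subsets we fit

`y ~ span * covariate_scaled + (1 | plot) + (1 | year_baseline) + (1 | year_comparison)`

by REML (`lme4`), with the covariate (sown plant species richness, or
land-use intensity smoothed over the sampling year and two predecessors
and averaged within each comparison) z-scored *once* on the full pair
table so that conditional slopes at raw levels (PSR 1 vs 60, LUI 0.5 vs
3.5) are comparable across subsets. The fixed-baseline scheme uses
ordinary least squares with the same fixed effects (its comparisons have
unique year pairs). Singular fits — common, since the generator has no
year-level shocks — report zero variance components and are counted,
never fatal; individual failed fits are redrawn and more than 5%
failures abort. Variance inflation factors of the fixed design are
computed and flagged at VIF ≥ 2.

Ensemble summaries are medians and 2.5/97.5 percentiles of the
coefficient and prediction distributions, with empirical two-sided P
values: twice the minority-side share of the point estimates, exact
zeros split evenly, reported as `P < 2/n` when one side is empty.
Predictions are back-transformed *before* summarizing; since medians
commute with monotone transforms this equals transforming the summary,
but percentile CIs do not, so the order matters and is fixed.

Two derived quantities drive the headline numbers. Component
contributions at horizon $h$: per model, the percentage share of the
predicted total change at $h$ (mean covariate) associated with richness
($\mathrm{SRE}_L + \mathrm{SRE}_G$), identity
($\mathrm{SIE}_L + \mathrm{SIE}_G$), all turnover, and the CDE; shares
are summarized across models and may exceed 100% or be negative because
each component has its own model. Percentage decline: the predicted
total-biomass loss at the last span divided by the mean baseline-period
(first five sampled years) biomass, annualized linearly (total/$h$; a
geometric option exists because "yearly decline" is ambiguous, and the
linear reading is the default).

## What the generator emulates — and what it cannot show

`synthetic_config()` encodes the two study designs: 80 experiment plots
on a sown-richness gradient (PSR 1, 2, 4, 8, 16, 60 allocated
14/16/16/16/14/4) sampled in 7 years between 2010 and 2020 with two
field replicates, and 150 real-world plots in three regions with yearly
LUI ~ Uniform(0.5, 3.5), 11 annual samplings, one pooled sample per
event. Species pools are bivariate log-normal in detection intensity and
body length with correlation `rho = -0.7` and `length_sdlog = 0.3`;
with the mass exponent 2.6 this makes large-bodied species rare *and*
below community-average in total contribution while above-average
individually — the configuration of rarity the analysis is designed to
detect. Declines are imposed as a yearly extinction hazard
`delta_rich = 0.10` weighted by rarity rank (`gamma = 1`) and body size
(`beta_size = 0.3`), plus `delta_abund = 0.02` yearly decay of
persisting species' intensities; hazards compound across calendar-year
gaps between samplings. Pool size rises with PSR and falls with LUI
(logit slope 0.3 around a base inclusion of 0.4), and the hazard is
modulated by the covariate (`rich_slope = 0.2`). These rates were set
from the closed forms — after 7 years, $1 - 0.9^7 \approx 52\%$ of
species lost against $\approx 6\%$ of persisting biomass — so that
roughly 90% of expected biomass loss is turnover-associated, and checked
once against the package's Monte-Carlo oracle
(`expected_components()`). The oracle simulates independent (baseline,
baseline + h) sample pairs — redrawing the species pool and plots every
replicate, so it marginalizes over the whole generative process — and
averages their partitions. Its default baselines are the years the
restricted design actually uses for span-h comparisons: with abundance
decay, detection is nonlinear in intensity, so component shares depend
on how far the baseline sits from the series start, and the oracle must
match the design-averaged estimand the ensemble recovers.

Detection is Poisson per season and replicate (effort 1, two seasons),
so the generator reproduces a key property of real samples: species
losses and gains partly reflect detection, not extinction — under a
stationary configuration the loss and gain terms are individually
nonzero but cancel. The `truth` table records which disappearances are
real extinctions versus detection failures, something field data cannot
do. The generator has no year-level climatic shocks, no spatial
autocorrelation, no within-season phenology and no overdispersion by
default; passing tests therefore certify the machinery and its
calibration under these idealized conditions, not robustness to those
real-data features.

## Numerical and design choices

* Tolerances: the partition's sum identity is checked to $10^{-9}$
  relative; oracle equivalence to $10^{-12}$ absolute.
* Empty communities: conventions above; a both-empty pair is all-zero,
  never an error.
* Poisson split draws exceeding $N$ are truncated to $N$, preserving
  feasibility of sampling without replacement.
* Season pooling happens after replicate assignment, preserving the
  per-event sampling structure; both orders are possible by
  restructuring the input, since splitting operates per event.
* Sample coverage uses the Chao singleton/doubleton form
  $C = 1 - \frac{f_1}{n}\frac{(n-1)f_1}{(n-1)f_1 + 2f_2}$, which reduces
  to Good–Turing $1 - f_1/n$ when $f_2 = 0$; the estimator choice is
  recorded per sample.
* Occupancy filters round the plot threshold up (10% of 85 plots means
  at least 9) and act per year, so a species may pass in some years
  only.
* The ensemble's problem sizes in the shipped analyses — 200 models for
  the main runs, 60–200 in the tests, oracle at 100–150 replicates —
  were chosen as the point where summaries stabilize (medians and CI
  endpoints move by far less than their width when doubling the
  ensemble); the study-scale choice of 1,000 models remains the
  documented default of `run_pipeline()`.
* Under the fixed-baseline scheme the no-reuse subsets may still contain
  several comparisons per plot (one per replicate chain plus controls);
  the scheme's OLS contract comes from its unique year pairs.

## Known limitations

Identity effects aggregate over species; the partition cannot say
*which* species drove them. Shares of predicted change are ratios of
separately fitted models and need not sum to 100%. The empirical P is a
resampling summary over overlapping subsets of one dataset, not a
frequentist test across datasets; the package's null-calibration test
shows it is conservative under the generator's conditions, but that is a
property of those conditions. Back-transformed predictions from the
signed-root scale are biased toward zero for noisy responses, and the
compression is stronger the larger a response's noise relative to its
mean; share ratios cancel much, not all, of it. Likewise the ensemble's
percentile CI spans subset-resampling variability of one dataset, not
sampling variability across datasets. Both effects are visible in the
parameter-recovery tests: CIs for the dominant, strongly varying
turnover share cover the generator's ground truth comfortably, while
coverage for the share of a noisy minority-signal component (persisting
species' abundance change under a purely abundance-driven decline)
falls short of nominal — a property of the estimation chain worth
keeping in mind when reading small component shares.
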