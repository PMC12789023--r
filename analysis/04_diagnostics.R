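#!/usr/bin/env Rscript

## Stage 4 -- diagnostics: per-sample coverage (Chao form of the
## Good-Turing family) and its temporal trend, the occupancy sensitivity
## filters (species in >= 10% / 30% of plots per year) re-partitioned,
## and the variance inflation of the fixed-effect design.

library(priceparts)

out <- "results"
allometry <- read_allometry("results/data/allometry.csv")

for (mode in c("experiment", "real_world")) {
  obs <- read_observations(
    file.path("results/data", paste0(mode, "_observations.csv")),
    allometry)
  if (all(obs$replicate == "full")) {
    set.seed(20260400)
    obs <- synthesize_replicates(obs)
  }
  ct <- coverage_table(obs)
  write_table(ct, file.path(out, paste0(mode, "_coverage.csv")))
  trend <- stats::coef(stats::lm(coverage ~ year, ct))[["year"]]
  message(sprintf("%s: mean coverage %.1f%%, trend %+.2f pp/yr",
                  mode, 100 * mean(ct$coverage), 100 * trend))

  ## occupancy sensitivity: how much of the partition survives filtering
  covariates <- read_covariates(
    file.path("results/data", paste0(mode, "_covariates.csv")))
  for (thr in c(0.10, 0.30)) {
    fobs <- suppressMessages(occupancy_filter(obs, thr))
    fv <- build_function_vectors(fobs, allometry)
    fvs <- function_vector_summary(fv)
    pairs <- attach_covariates(
      enumerate_pairs(fvs, "restricted_moving_average"), covariates)
    part <- partition_batch(pairs, fv)
    write_table(part, file.path(out, sprintf("%s_partitions_occ%02.0f.csv",
                                             mode, 100 * thr)))
    message(sprintf(
      "%s occ>=%.0f%%: %d of %d species-year combos kept, %d comparisons",
      mode, 100 * thr,
      length(unique(paste(fobs$year, fobs$species_id))),
      length(unique(paste(obs$year, obs$species_id))), nrow(part)))
  }

  ## multicollinearity of the fixed design on the full pair table
  part <- utils::read.csv(file.path(out, paste0(mode, "_partitions.csv")))
  z <- (part$covariate - mean(part$covariate)) / stats::sd(part$covariate)
  vif <- variance_inflation(cbind(span = part$span, covariate = z,
                                  interaction = part$span * z))
  message(sprintf("%s: VIF span %.2f, covariate %.2f, interaction %.2f%s",
                  mode, vif[1], vif[2], vif[3],
                  if (any(vif >= 2)) "  [>= 2 flagged]" else ""))
}
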