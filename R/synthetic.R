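#' Configuration of the synthetic community generator
#'
#' Builds a validated configuration for simulating grassland arthropod
#' community time series with the statistical structure the partitioning
#' analysis assumes: log-normally distributed species abundances, body
#' length negatively correlated with abundance (large-bodied species are
#' typically rare), plot-level species pools modulated by the environment
#' (sown plant species richness PSR in experiment mode, land-use intensity
#' LUI in real-world mode), rarity- and size-weighted species extinction,
#' abundance decay of persisting species, and Poisson detection per
#' season and replicate.
#'
#' @param mode `"experiment"` (80 plots on a sown PSR gradient
#'   {1,2,4,8,16,60} with allocation 14/16/16/16/14/4, two field
#'   replicates) or `"real_world"` (150 plots in 3 regions, yearly LUI ~
#'   Uniform(0.5, 3.5), single pooled sample per event).
#' @param n_plots Number of plots (defaults by mode).
#' @param years Sampling years (defaults: the experimental series' 7
#'   sampling years 2010-2020 with gaps, or 11 annual years 2008-2018 in
#'   real-world mode).
#' @param seasons Season labels sampled per year.
#' @param n_species Regional species pool size.
#' @param abund_meanlog,abund_sdlog Log-normal detection-intensity
#'   distribution of the pool (mean expected individuals per species per
#'   season per replicate at effort 1).
#' @param length_meanlog,length_sdlog Log-normal body length (mm)
#'   distribution.
#' @param rho Correlation between log length and log abundance (in
#'   \[-1, 0\]).
#' @param delta_rich Yearly extinction hazard (mean probability that a
#'   persisting species goes locally extinct).
#' @param gamma Rarity-rank weight exponent of the extinction hazard
#'   (0 = uniform extinction across species).
#' @param beta_size Extra extinction weight on large-bodied species (log
#'   scale per SD of log length; 0 = none).
#' @param delta_abund Yearly proportional decline of persisting species'
#'   detection intensities.
#' @param incl_base Local-pool inclusion probability at the mean
#'   covariate.
#' @param incl_slope Logit-scale effect of the standardized covariate on
#'   local-pool inclusion (positive: richer pools at high PSR; applied
#'   with a negative sign to standardized LUI).
#' @param rich_slope Multiplicative modulation of `delta_rich` by the
#'   standardized covariate.
#' @param effort Sampling effort multiplier of the Poisson detection
#'   rates.
#' @param replicate_mode `"field"` (two replicates A/B drawn per event) or
#'   `"synthetic_split"` (one pooled sample per event, labelled "full",
#'   for downstream [synthesize_replicates()]).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(mode = c("experiment", "real_world"),
                             n_plots = NULL, years = NULL,
                             seasons = c("spring", "summer"),
                             n_species = 300,
                             abund_meanlog = log(0.4), abund_sdlog = 1.3,
                             length_meanlog = log(4), length_sdlog = 0.3,
                             rho = -0.7,
                             delta_rich = 0.10, gamma = 1,
                             beta_size = 0.3, delta_abund = 0.02,
                             incl_base = 0.4, incl_slope = 0.3,
                             rich_slope = 0.2, effort = 1,
                             replicate_mode = c("field",
                                                "synthetic_split")) {
  mode <- match.arg(mode)
  replicate_mode <- match.arg(replicate_mode)
  if (is.null(n_plots)) n_plots <- if (mode == "experiment") 80L else 150L
  if (is.null(years))
    years <- if (mode == "experiment")
      c(2010L, 2012L, 2014L, 2016L, 2017L, 2019L, 2020L) else 2008:2018
  if (rho < -1 || rho > 0)
    stop("synthetic_config: rho must be in [-1, 0]", call. = FALSE)
  for (nm in c("delta_rich", "gamma", "beta_size", "delta_abund",
               "effort", "n_species"))
    if (get(nm) < 0)
      stop("synthetic_config: ", nm, " must be >= 0", call. = FALSE)
  cfg <- list(mode = mode, n_plots = as.integer(n_plots),
              years = sort(as.integer(years)), seasons = seasons,
              n_species = as.integer(n_species),
              abund_meanlog = abund_meanlog, abund_sdlog = abund_sdlog,
              length_meanlog = length_meanlog,
              length_sdlog = length_sdlog, rho = rho,
              delta_rich = delta_rich, gamma = gamma,
              beta_size = beta_size, delta_abund = delta_abund,
              incl_base = incl_base, incl_slope = incl_slope,
              rich_slope = rich_slope, effort = effort,
              replicate_mode = replicate_mode)
  if (mode == "experiment") {
    cfg$psr_levels <- c(1L, 2L, 4L, 8L, 16L, 60L)
    cfg$psr_allocation <- c(14L, 16L, 16L, 16L, 14L, 4L)
    if (n_plots == 80L) {
      ## the reference design
    } else {
      ## rescale the allocation proportionally for non-standard sizes
      alloc <- round(cfg$psr_allocation / 80 * n_plots)
      alloc[1] <- n_plots - sum(alloc[-1])
      if (any(alloc < 0))
        stop("synthetic_config: n_plots too small for the PSR allocation",
             call. = FALSE)
      cfg$psr_allocation <- as.integer(alloc)
    }
    if (sum(cfg$psr_allocation) != n_plots)
      stop("synthetic_config: PSR allocation must sum to n_plots",
           call. = FALSE)
  } else {
    cfg$lui_range <- c(0.5, 3.5)
    cfg$n_regions <- 3L
  }
  structure(cfg, class = "synthetic_config")
}

## Taxon groups with their guild assignment; Coleoptera species are split
## across guilds, the others are guild-fixed.
TAXON_TABLE <- data.frame(
  taxon_group = c("Coleoptera", "Hemiptera", "Araneae-hunting",
                  "Araneae-web", "Hymenoptera", "Orthoptera"),
  prop = c(0.35, 0.25, 0.12, 0.08, 0.12, 0.08),
  guild = c(NA, "herbivore", "predator", "predator", "other", "herbivore"))

#' Draw a regional species pool
#'
#' Species detection intensities and body lengths come from the
#' configured bivariate log-normal with negative correlation (rare species
#' tend to be large-bodied); taxon groups and guilds are assigned by fixed
#' proportions. Uses the current RNG state.
#'
#' @param config A [synthetic_config()].
#' @return Data frame `species_id, intensity, body_length_mm, taxon_group,
#'   guild, z_len` (standardized log length).
#' @export
build_species_pool <- function(config) {
  s <- config$n_species
  z1 <- stats::rnorm(s)
  z2 <- stats::rnorm(s)
  log_abund <- config$abund_meanlog + config$abund_sdlog * z1
  zl <- config$rho * z1 + sqrt(1 - config$rho^2) * z2
  log_len <- config$length_meanlog + config$length_sdlog * zl
  taxon <- sample(TAXON_TABLE$taxon_group, s, replace = TRUE,
                  prob = TAXON_TABLE$prop)
  guild <- TAXON_TABLE$guild[match(taxon, TAXON_TABLE$taxon_group)]
  guild[is.na(guild)] <- sample(c("herbivore", "predator", "other"),
                                sum(is.na(guild)), replace = TRUE,
                                prob = c(0.5, 0.3, 0.2))
  data.frame(species_id = sprintf("sp%04d", seq_len(s)),
             intensity = exp(log_abund),
             body_length_mm = exp(log_len),
             taxon_group = taxon, guild = guild, z_len = zl)
}

## Plot frame: ids, regions and the standardized covariate driving pool
## size and hazard modulation. Experiment: standardized log2(PSR);
## real-world: standardized plot-mean LUI (flipped sign for inclusion so
## that high LUI means poorer pools).
synthetic_plots <- function(config) {
  if (config$mode == "experiment") {
    psr <- rep(config$psr_levels, config$psr_allocation)
    plots <- data.frame(plot_id = sprintf("p%03d", seq_len(config$n_plots)),
                        region = "main", psr = psr)
    lv <- log2(plots$psr)
    plots$cov_std <- (lv - mean(lv)) / stats::sd(lv)
    plots$incl_std <- plots$cov_std
  } else {
    plots <- data.frame(plot_id = sprintf("p%03d", seq_len(config$n_plots)),
                        region = rep(sprintf("R%d", seq_len(config$n_regions)),
                                     length.out = config$n_plots))
    lui <- matrix(stats::runif(config$n_plots * length(config$years),
                               config$lui_range[1], config$lui_range[2]),
                  nrow = config$n_plots)
    plots$lui_mean <- rowMeans(lui)
    plots$cov_std <- (plots$lui_mean - mean(config$lui_range)) /
      (diff(config$lui_range) / sqrt(12))
    plots$incl_std <- -plots$cov_std
    attr(plots, "lui") <- lui
  }
  plots
}

## Latent per-plot trajectories: local pool membership, survival and
## decayed intensities at the sampled timepoints. `elapsed` holds the
## calendar-year offsets of the timepoints from the series start; the
## yearly hazard compounds over year gaps between samplings.
simulate_latents <- function(config, pool, plots, elapsed) {
  n_steps <- length(elapsed)
  lapply(seq_len(nrow(plots)), function(p) {
    p_incl <- stats::plogis(stats::qlogis(config$incl_base) +
                              config$incl_slope * plots$incl_std[p])
    local <- which(stats::runif(config$n_species) < p_incl)
    n_loc <- length(local)
    alive <- matrix(TRUE, n_loc, n_steps)
    if (n_loc > 0 && n_steps > 1 && config$delta_rich > 0) {
      d_rich <- config$delta_rich *
        max(0, 1 + config$rich_slope * plots$cov_std[p])
      rank_w <- (rank(-pool$intensity[local],
                      ties.method = "first") / n_loc)^config$gamma
      w <- rank_w * exp(config$beta_size * pool$z_len[local])
      h <- pmin(1, d_rich * w / mean(w))
      for (t in 2:n_steps) {
        surv <- (1 - h)^(elapsed[t] - elapsed[t - 1])
        alive[, t] <- alive[, t - 1] & (stats::runif(n_loc) < surv)
      }
    }
    list(local = local, alive = alive)
  })
}

#' Simulate a synthetic arthropod observation table
#'
#' Draws a regional pool, plot-level local pools, yearly extinction and
#' abundance decay, and Poisson detection counts per plot, year, season
#' and replicate. With all decline rates zero the process is stationary.
#' Uses the current RNG state; seed with [set.seed()] for bit-identical
#' tables.
#'
#' @param config A [synthetic_config()].
#' @return A list with `observations` (validated observation table),
#'   `covariates` (PSR or yearly LUI table), `pool` (the regional pool)
#'   and `truth` (latent per plot/year/species states: alive and
#'   detection intensity, separating real extinctions from detection
#'   failures).
#' @export
simulate_observations <- function(config) {
  pool <- build_species_pool(config)
  plots <- synthetic_plots(config)
  years <- config$years
  n_steps <- length(years)
  replicates <- if (config$replicate_mode == "field") c("A", "B") else "full"
  elapsed <- years - min(years)
  lat <- simulate_latents(config, pool, plots, elapsed)
  decay <- (1 - config$delta_abund)^elapsed

  obs_chunks <- vector("list", nrow(plots) * n_steps)
  truth_chunks <- vector("list", nrow(plots))
  k <- 0L
  for (p in seq_len(nrow(plots))) {
    local <- lat[[p]]$local
    alive <- lat[[p]]$alive
    n_loc <- length(local)
    truth_chunks[[p]] <- if (n_loc) data.frame(
      plot_id = plots$plot_id[p],
      year = rep(years, each = n_loc),
      species_id = pool$species_id[local],
      alive = as.vector(alive),
      intensity = as.vector(outer(pool$intensity[local], decay) * alive))
    if (n_loc == 0) { k <- k + n_steps; next }
    for (t in seq_len(n_steps)) {
      lam <- pool$intensity[local] * decay[t] * alive[, t] * config$effort
      n_cells <- length(config$seasons) * length(replicates)
      counts <- matrix(stats::rpois(n_loc * n_cells, rep(lam, n_cells)),
                       nrow = n_loc)
      cells <- expand.grid(season = config$seasons, replicate = replicates,
                           stringsAsFactors = FALSE)
      nz <- which(counts > 0, arr.ind = TRUE)
      k <- k + 1L
      if (nrow(nz) == 0) next
      sp <- local[nz[, 1]]
      obs_chunks[[k]] <- data.frame(
        plot_id = plots$plot_id[p], region = plots$region[p],
        year = years[t], season = cells$season[nz[, 2]],
        replicate = cells$replicate[nz[, 2]],
        species_id = pool$species_id[sp],
        taxon_group = pool$taxon_group[sp], guild = pool$guild[sp],
        count = counts[nz], body_length_mm = pool$body_length_mm[sp])
    }
  }
  obs <- do.call(rbind, obs_chunks)
  if (is.null(obs)) obs <- validate_observations(
    stats::setNames(data.frame(character(), character(), integer(),
                               character(), character(), character(),
                               character(), character(), integer(),
                               numeric()), OBS_COLS))
  obs <- obs[order(obs$plot_id, obs$year, obs$season, obs$replicate,
                   obs$species_id), ]
  rownames(obs) <- NULL

  covariates <- if (config$mode == "experiment") {
    plots[c("plot_id", "psr")]
  } else {
    lui <- attr(plots, "lui")
    data.frame(plot_id = rep(plots$plot_id, times = n_steps),
               year = rep(years, each = nrow(plots)),
               lui = as.vector(lui))
  }
  list(observations = validate_observations(obs),
       covariates = validate_covariates(covariates),
       pool = pool,
       truth = do.call(rbind, truth_chunks))
}

#' Monte-Carlo oracle for the expected Price components
#'
#' Estimates the expected value of each partition component (and of the
#' component shares of total biomass change) at time span `horizon` by
#' simulating `n_oracle` independent (baseline, baseline + horizon)
#' sample pairs per plot from the configured process and averaging their
#' partitions. This is the ground truth against which ensemble parameter
#' recovery is checked.
#'
#' By default the baseline years are those the restricted comparison
#' design would actually use for span-h comparisons (sampled years among
#' the first five whose year + h is also sampled), so the oracle matches
#' the design-averaged estimand; with abundance decay, detection is
#' nonlinear in intensity and the component shares depend on how far the
#' baseline sits from the series start, so this alignment matters. Pass
#' `baseline_years = min(config$years)` for the process-start quantity.
#'
#' @param config A [synthetic_config()].
#' @param horizon Time span h in years.
#' @param n_oracle Number of independent replicate simulations (>= 100
#'   for stable shares).
#' @param mode Function-vector mode (see [build_function_vectors()]).
#' @param baseline_years Calendar baseline years to average over
#'   (default: the design-eligible span-h baselines).
#' @return A list with `components` (mean and standard error of each
#'   component and of `delta_T`, in mg per sample), `shares` (percentage
#'   of expected total change associated with richness, identity, all
#'   turnover, and persisting-species abundance change), and
#'   `baseline_T` (mean baseline total biomass).
#' @export
expected_components <- function(config, horizon, n_oracle = 200,
                                mode = "total_biomass",
                                baseline_years = NULL) {
  if (is.null(baseline_years)) {
    first5 <- utils::head(sort(config$years), 5)
    baseline_years <- first5[(first5 + horizon) %in% config$years]
    if (!length(baseline_years)) baseline_years <- min(config$years)
  }
  base_elapsed <- baseline_years - min(config$years)
  elapsed <- sort(unique(c(base_elapsed, base_elapsed + horizon)))
  t_b <- match(base_elapsed, elapsed)
  t_c <- match(base_elapsed + horizon, elapsed)
  decay <- (1 - config$delta_abund)^elapsed
  comp_cols <- c(PRICE_COMPONENTS, "delta_T")
  rep_means <- matrix(NA_real_, n_oracle, length(comp_cols),
                      dimnames = list(NULL, comp_cols))
  base_T <- numeric(n_oracle)
  for (r in seq_len(n_oracle)) {
    ## one full process replicate: fresh pool, plots and trajectories, so
    ## the expectation marginalizes over the whole generative process
    pool <- build_species_pool(config)
    plots <- synthetic_plots(config)
    mass_all <- synthetic_mass(pool)
    n_pairs <- nrow(plots) * length(base_elapsed)
    lat <- simulate_latents(config, pool, plots, elapsed)
    acc <- numeric(length(comp_cols))
    names(acc) <- comp_cols
    tb <- 0
    for (p in seq_along(lat)) {
      local <- lat[[p]]$local
      if (!length(local)) next
      lam <- pool$intensity[local] * config$effort *
        length(config$seasons)
      mass <- mass_all[local]
      for (k in seq_along(base_elapsed)) {
        lam_b <- lam * decay[t_b[k]] * lat[[p]]$alive[, t_b[k]]
        lam_c <- lam * decay[t_c[k]] * lat[[p]]$alive[, t_c[k]]
        c0 <- stats::rpois(length(local), lam_b)
        ch <- stats::rpois(length(local), lam_c)
        zb <- if (mode == "total_biomass") c0 * mass else mass
        zc <- if (mode == "total_biomass") ch * mass else mass
        b <- stats::setNames(zb, pool$species_id[local])[c0 > 0]
        co <- stats::setNames(zc, pool$species_id[local])[ch > 0]
        part <- price_partition(b, co)
        acc <- acc + unlist(part[comp_cols])
        tb <- tb + part$T_baseline
      }
    }
    rep_means[r, ] <- acc / n_pairs
    base_T[r] <- tb / n_pairs
  }
  means <- colMeans(rep_means)
  ses <- apply(rep_means, 2, stats::sd) / sqrt(n_oracle)
  shares <- c(
    richness = 100 * (means[["sre_loss"]] + means[["sre_gain"]]) /
      means[["delta_T"]],
    identity = 100 * (means[["sie_loss"]] + means[["sie_gain"]]) /
      means[["delta_T"]],
    turnover = 100 * (means[["sre_loss"]] + means[["sre_gain"]] +
                        means[["sie_loss"]] + means[["sie_gain"]]) /
      means[["delta_T"]],
    cde = 100 * means[["cde"]] / means[["delta_T"]])
  list(components = data.frame(component = comp_cols, mean = means,
                               se = ses, row.names = NULL),
       shares = shares,
       baseline_T = mean(base_T),
       horizon = horizon, n_oracle = n_oracle)
}

## Individual dry mass of the synthetic pool via the shipped placeholder
## allometry (a = 0.05, b = 2.6 for every group).
synthetic_mass <- function(pool) {
  synthetic_allometry()$a[1] * pool$body_length_mm^
    synthetic_allometry()$b[1]
}

#' Placeholder allometric table of the synthetic taxa
#'
#' A synthetic stand-in with one shared coefficient pair (a = 0.05,
#' b = 2.6, typical of arthropod length-mass regressions); users analysing
#' real data must supply literature coefficients per taxon group.
#'
#' @return Allometric table covering the synthetic taxon groups.
#' @export
synthetic_allometry <- function() {
  data.frame(taxon_group = TAXON_TABLE$taxon_group, a = 0.05, b = 2.6)
}
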