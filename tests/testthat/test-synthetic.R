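test_that("species pools have the configured size-abundance correlation", {
  set.seed(12)
  cfg <- synthetic_config("experiment", n_species = 1000, rho = -0.5)
  pool <- build_species_pool(cfg)
  r <- cor(log(pool$intensity), log(pool$body_length_mm))
  expect_lt(abs(r - (-0.5)), 0.1)
  cfg0 <- synthetic_config("experiment", n_species = 1000, rho = 0)
  r0 <- cor(log(build_species_pool(cfg0)$intensity),
            log(build_species_pool(cfg0)$body_length_mm))
  expect_lt(abs(r0), 0.1)
  expect_error(synthetic_config("experiment", rho = 0.3), "rho")
  one <- build_species_pool(synthetic_config("experiment", n_species = 1))
  expect_identical(nrow(one), 1L)
})

test_that("generated tables pass validation across random configs", {
  set.seed(23)
  for (i in 1:8) {
    cfg <- synthetic_config(
      sample(c("experiment", "real_world"), 1),
      n_plots = sample(c(8, 12), 1), n_species = sample(c(20, 50), 1),
      years = sort(sample(2008:2018, sample(2:4, 1))),
      delta_rich = runif(1, 0, 0.2), delta_abund = runif(1, 0, 0.1),
      gamma = runif(1, 0, 2), beta_size = runif(1, 0, 0.5),
      rho = -runif(1))
    sim <- simulate_observations(cfg)
    expect_silent(validate_observations(sim$observations))
    expect_silent(validate_covariates(sim$covariates))
    expect_true(all(sim$observations$count >= 1))
    ## truth separates latent state from detection
    expect_true(all(c("alive", "intensity") %in% names(sim$truth)))
  }
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- synthetic_config("experiment", n_plots = 8, n_species = 40,
                          years = c(2010, 2012))
  set.seed(9)
  a <- simulate_observations(cfg)
  set.seed(9)
  b <- simulate_observations(cfg)
  expect_identical(a$observations, b$observations)
  expect_identical(a$covariates, b$covariates)
})

test_that("a stationary configuration has no richness or count trend", {
  set.seed(31)
  cfg <- synthetic_config("experiment", n_plots = 16, n_species = 120,
                          years = 2010:2015, delta_rich = 0,
                          delta_abund = 0, rich_slope = 0)
  slopes_s <- slopes_n <- numeric(8)
  for (i in 1:8) {
    sim <- simulate_observations(cfg)
    obs <- sim$observations
    per_year <- aggregate(cbind(n = obs$count) ~ year, obs, sum)
    rich <- aggregate(species_id ~ year, obs,
                      function(x) length(unique(x)))
    slopes_n[i] <- coef(lm(n ~ year, per_year))[["year"]]
    slopes_s[i] <- coef(lm(species_id ~ year, rich))[["year"]]
  }
  ## across replicate simulations the mean trend is zero
  expect_lt(abs(mean(slopes_n)), 3 * sd(slopes_n) / sqrt(8))
  expect_lt(abs(mean(slopes_s)), 3 * sd(slopes_s) / sqrt(8))
})

test_that("abundance decline halves detections at the configured rate", {
  set.seed(41)
  cfg <- synthetic_config("experiment", n_plots = 40, n_species = 30,
                          years = c(2010, 2011), delta_rich = 0,
                          delta_abund = 0.5, rich_slope = 0, effort = 2)
  sim <- simulate_observations(cfg)
  obs <- sim$observations
  n0 <- sum(obs$count[obs$year == 2010])
  n1 <- sum(obs$count[obs$year == 2011])
  ## expected halving; Poisson noise over thousands of counts is small
  expect_lt(abs(n1 / n0 - 0.5), 0.05)
})

test_that("oracle components vanish under stationarity", {
  set.seed(52)
  cfg <- synthetic_config("experiment", n_plots = 10, n_species = 60,
                          delta_rich = 0, delta_abund = 0, rich_slope = 0)
  orc <- expected_components(cfg, horizon = 3, n_oracle = 60)
  comp <- orc$components
  m <- stats::setNames(comp$mean, comp$component)
  se <- stats::setNames(comp$se, comp$component)
  ## baseline and comparison are exchangeable: the net quantities vanish;
  ## the individual loss/gain terms carry symmetric detection turnover
  ## that cancels pairwise
  expect_lt(abs(m[["delta_T"]]), 3 * se[["delta_T"]] + 1e-9)
  expect_lt(abs(m[["cde"]]), 3 * se[["cde"]] + 1e-9)
  expect_lt(abs(m[["sre_loss"]] + m[["sre_gain"]]),
            3 * (se[["sre_loss"]] + se[["sre_gain"]]) + 1e-9)
  expect_lt(abs(m[["sie_loss"]] + m[["sie_gain"]]),
            3 * (se[["sie_loss"]] + se[["sie_gain"]]) + 1e-9)
  ## detection turnover is present but symmetric
  expect_lt(m[["sre_loss"]], 0)
  expect_gt(m[["sre_gain"]], 0)
})

test_that("uniform extinction leaves identity components near zero", {
  set.seed(63)
  cfg <- synthetic_config("experiment", n_plots = 12, n_species = 80,
                          delta_rich = 0.15, gamma = 0, beta_size = 0,
                          delta_abund = 0, rich_slope = 0)
  orc <- expected_components(cfg, horizon = 3, n_oracle = 80)
  comp <- orc$components
  for (cc in c("sie_loss", "sie_gain")) {
    row <- comp[comp$component == cc, ]
    expect_lt(abs(row$mean), 3 * row$se + 0.05 * abs(
      comp$mean[comp$component == "sre_loss"]))
  }
  ## richness loss clearly dominates
  expect_lt(comp$mean[comp$component == "sre_loss"], 0)
})

test_that("size-biased extinction shifts identity loss monotonically", {
  ## a pool where body size carries biomass signal (weak size-abundance
  ## correlation, wide size spread), so losing large-bodied species
  ## removes above-average total contributions; at the package defaults
  ## the size-total-biomass covariance is deliberately near zero and the
  ## size bias would have nothing to act on
  set.seed(74)
  offsets <- vapply(c(0, 0.6, 1.2), function(bs) {
    cfg <- synthetic_config("experiment", n_plots = 12, n_species = 80,
                            rho = -0.3, length_sdlog = 0.5,
                            delta_rich = 0.2, gamma = 0, beta_size = bs,
                            delta_abund = 0, rich_slope = 0)
    orc <- expected_components(cfg, horizon = 3, n_oracle = 60)
    orc$components$mean[orc$components$component == "sie_loss"]
  }, numeric(1))
  ## stronger size bias -> larger-bodied species lost -> identity-loss
  ## offset grows in magnitude
  expect_true(abs(offsets[3]) > abs(offsets[1]))
})
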