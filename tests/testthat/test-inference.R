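test_that("signed square root is odd, increasing and exactly invertible", {
  expect_identical(sqrt_signed(0), 0)
  expect_equal(sqrt_signed(-9), -3)
  expect_equal(sqrt_signed_inv(-3), -9)
  set.seed(8)
  x <- runif(1000, -50, 50)
  expect_equal(sqrt_signed_inv(sqrt_signed(x)), x, tolerance = 1e-12)
  expect_true(all(diff(sqrt_signed(sort(x))) >= 0))
  expect_equal(sqrt_signed(-x), -sqrt_signed(x))
})

test_that("empirical P doubles the minority side and caps at 1", {
  expect_equal(empirical_p(c(rep(1, 500), rep(-1, 500))), 1)
  expect_equal(empirical_p(c(rep(1, 975), rep(-1, 25))), 0.05)
  all_pos <- empirical_p(rep(1, 1000))
  expect_equal(as.numeric(all_pos), 0)
  expect_equal(attr(all_pos, "p_bound"), 0.002)
  ## zeros split evenly between the sides
  expect_equal(empirical_p(c(0, 0)), 1)
  expect_equal(as.numeric(empirical_p(c(1, 1, 0, 0))), 0.5)
  expect_error(empirical_p(numeric(0)), "empty")
})

test_that("component model recovers known fixed effects", {
  set.seed(90)
  n <- 400
  df <- data.frame(span = sample(0:7, n, TRUE),
                   cov_z = rnorm(n),
                   plot_id = sample(paste0("p", 1:20), n, TRUE))
  df$year_b <- sample(2010:2016, n, TRUE)
  df$year_c <- df$year_b + df$span
  ## response already on the transformed scale: invert so the model's
  ## internal transform recovers it
  y <- 0.5 * df$span + rnorm(n, 0, 0.01)
  df$resp <- sqrt_signed_inv(y)
  fit <- fit_component_model(df, "resp", "mixed")
  expect_lt(abs(fit$coef[["span"]] - 0.5), 0.01)
  ## OLS oracle on the same rows (no random-effect structure to speak of)
  ols <- coef(lm(y ~ span * cov_z, df))
  expect_lt(abs(fit$coef[["span"]] - ols[["span"]]), 0.02)
  ## exact interaction: y = span * cov_z
  df$resp2 <- sqrt_signed_inv(df$span * df$cov_z)
  fit2 <- fit_component_model(df, "resp2", "fixed_baseline")
  expect_equal(fit2$coef[["span:cov"]], 1, tolerance = 1e-8)
  expect_equal(fit2$coef[["span"]], 0, tolerance = 1e-8)
  ## constant response: intercept only, zero slopes, flagged singular
  df$resp3 <- sqrt_signed_inv(rep(2, n))
  fit3 <- fit_component_model(df, "resp3", "mixed")
  expect_equal(fit3$coef[["intercept"]], 2, tolerance = 1e-6)
  expect_equal(fit3$coef[["span"]], 0, tolerance = 1e-6)
  expect_true(fit3$singular)
  expect_error(fit_component_model(df[1:3, ], "resp"), "fewer rows")
})

test_that("conditional slopes combine main and interaction terms", {
  cf <- c(intercept = 0, span = 1, cov = 0.3, `span:cov` = 2)
  ## z(x) = 0.5 at x = 3 with mean 2, sd 2
  expect_equal(unname(conditional_slopes(cf, 3, 2, 2)), 2)
  no_int <- c(intercept = 0, span = 1.2, cov = 0.3, `span:cov` = 0)
  s <- conditional_slopes(no_int, c(1, 60), 10, 5)
  expect_equal(unname(s), c(1.2, 1.2))
  expect_error(conditional_slopes(cf, 3, NA, 2), "scaling")
})

test_that("a degenerate one-model ensemble equals its single fit", {
  set.seed(14)
  keys <- key_frame(paste0("p", 1:6), c(2010, 2012, 2014))
  pairs <- enumerate_pairs(keys, "moving_average", min_replicates = 1)
  pairs <- attach_covariates(pairs, data.frame(plot_id = paste0("p", 1:6),
                                               psr = c(1, 2, 4, 8, 16, 60)))
  pairs$delta_T <- rnorm(nrow(pairs), -1, 2)
  ens <- ensemble_inference(pairs, "delta_T", n_models = 1,
                            flip_controls = FALSE)
  est <- ens$estimates
  expect_true(all(est$ci_low == est$median & est$ci_high == est$median))
  ## identical response everywhere: zero-width CIs, zero slopes
  pairs$flat <- 4
  ens2 <- ensemble_inference(pairs, "flat", n_models = 5)
  est2 <- ens2$estimates
  expect_true(all(abs(est2$median[est2$term == "span"]) < 1e-6))
  expect_true(all(est2$ci_high - est2$ci_low < 1e-6))
  pred <- ens2$predictions
  expect_equal(pred$median[pred$span == 0 &
                             pred$covariate_level == "mean"][1], 4,
               tolerance = 1e-6)
})

test_that("ensemble summaries are invariant to fit order", {
  set.seed(77)
  arr <- array(rnorm(60), dim = c(20, 1, 3),
               dimnames = list(NULL, "delta_T", c("a", "b", "c")))
  med1 <- apply(arr[, 1, ], 2, median)
  perm <- sample(20)
  med2 <- apply(arr[perm, 1, ], 2, median)
  expect_equal(med1, med2)
  p1 <- empirical_p(arr[, 1, 1])
  p2 <- empirical_p(arr[perm, 1, 1])
  expect_equal(as.numeric(p1), as.numeric(p2))
})

test_that("contribution shares follow the worked partition arithmetic", {
  ## single-model ensemble built by hand: components (-4, -2, 2, -1, -1),
  ## delta_T = -6 at the horizon
  comps <- c(sre_loss = -4, sie_loss = -2, sre_gain = 2, sie_gain = -1,
             cde = -1, delta_T = -6)
  arr <- array(NA_real_, dim = c(1, 6, 2, 1),
               dimnames = list(NULL, names(comps), c("0", "7"), "mean"))
  arr[1, , "0", 1] <- 0
  arr[1, , "7", 1] <- comps
  ens <- structure(list(pred_array = arr), class = "price_ensemble")
  ct <- component_contributions(ens, 7)
  expect_equal(ct$median[ct$group == "turnover"], 100 * 5 / 6)
  expect_equal(ct$median[ct$group == "cde"], 100 * 1 / 6)
  expect_equal(ct$median[ct$group == "turnover"] +
                 ct$median[ct$group == "cde"], 100)
  expect_equal(ct$median[ct$group == "richness"], 100 * 2 / 6)
  expect_equal(ct$median[ct$group == "identity"], 100 * 3 / 6)
  ## all identity and abundance predictions zero: richness takes all
  arr0 <- arr
  arr0[1, c("sie_loss", "sie_gain", "cde"), "7", 1] <- 0
  arr0[1, "delta_T", "7", 1] <- -2
  ens0 <- structure(list(pred_array = arr0), class = "price_ensemble")
  ct0 <- component_contributions(ens0, 7)
  expect_equal(ct0$median[ct0$group == "richness"], 100)
  ## zero-denominator models are excluded with a message
  arrz <- arr
  arrz[1, "delta_T", "7", 1] <- 0
  ensz <- structure(list(pred_array = arrz), class = "price_ensemble")
  expect_message(ctz <- component_contributions(ensz, 7), "excluded")
  expect_true(all(is.na(ctz$median)))
})

test_that("shares sum to 100% whenever the denominator is nonzero", {
  set.seed(55)
  n_m <- 30
  arr <- array(NA_real_, dim = c(n_m, 6, 1, 1),
               dimnames = list(NULL, c("sre_loss", "sie_loss", "sre_gain",
                                       "sie_gain", "cde", "delta_T"),
                               "7", "mean"))
  comps <- matrix(rnorm(n_m * 5), n_m)
  arr[, 1:5, 1, 1] <- comps
  arr[, 6, 1, 1] <- rowSums(comps)
  ens <- structure(list(pred_array = arr), class = "price_ensemble")
  ct <- component_contributions(ens, 7)
  ## per-model turnover + cde share identity propagates to the medians of
  ## the summed groups only when computed per model; check via quantile
  ## identity on a direct recomputation
  share_turn <- 100 * rowSums(comps[, 1:4]) / arr[, 6, 1, 1]
  share_cde <- 100 * comps[, 5] / arr[, 6, 1, 1]
  expect_equal(share_turn + share_cde, rep(100, n_m))
  expect_equal(ct$median[ct$group == "turnover"], median(share_turn))
})

test_that("percentage decline divides predicted loss by baseline biomass", {
  arr <- array(NA_real_, dim = c(3, 1, 1, 1),
               dimnames = list(NULL, "delta_T", "7", "mean"))
  arr[, 1, 1, 1] <- c(-0.35, -0.35, -0.35)
  ens <- structure(list(pred_array = arr), class = "price_ensemble")
  d <- percent_decline(ens, baseline_mean = 1, horizon = 7)
  expect_equal(d$total_pct, 35)
  expect_equal(d$yearly_pct, 5)
  dz <- percent_decline(structure(list(pred_array = arr * 0),
                                  class = "price_ensemble"), 1, 7)
  expect_equal(dz$total_pct, 0)
  ## per-model propagation matches direct recomputation on a toy ensemble
  arr3 <- arr
  arr3[, 1, 1, 1] <- c(-0.2, -0.4, -0.6)
  ens3 <- structure(list(pred_array = arr3), class = "price_ensemble")
  d3 <- percent_decline(ens3, 2, 7)
  expect_equal(d3$total_pct, median(100 * c(0.2, 0.4, 0.6) / 2))
  expect_equal(d3$total_ci_low,
               unname(quantile(100 * c(0.2, 0.4, 0.6) / 2, 0.025)))
  g <- percent_decline(ens3, 2, 7, annualization = "geometric")
  expect_equal(g$yearly_pct, 100 * (1 - (1 - 0.2)^(1 / 7)))
  expect_error(percent_decline(ens3, 0, 7), "> 0")
})
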