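#' Signed square-root transform and its inverse
#'
#' Community change responses are symmetric around zero with few extreme
#' values; the transform takes the square root of the absolute value and
#' reconstructs the sign, i.e. sign(x) * sqrt(|x|). Both the transform and
#' its inverse sign(y) * y^2 are odd and strictly increasing.
#'
#' @param x,y Numeric vectors.
#' @return Transformed values.
#' @export
sqrt_signed <- function(x) sign(x) * sqrt(abs(x))

#' @rdname sqrt_signed
#' @export
sqrt_signed_inv <- function(y) sign(y) * y^2

#' Empirical two-sided P value of a resampled estimate distribution
#'
#' Twice the proportion of estimates falling on the less frequent side of
#' zero, capped at 1. Exact zeros are split evenly between the two sides.
#' When one side is empty the value 0 is returned with attribute
#' `p_bound = 2/n` (the resolution bound, to be reported as "P < 2/n").
#'
#' @param estimates Numeric vector of resampled point estimates.
#' @return The empirical P, with attribute `p_bound`.
#' @export
empirical_p <- function(estimates) {
  n <- length(estimates)
  if (n == 0) stop("empirical_p: empty estimate vector", call. = FALSE)
  nz <- sum(estimates == 0)
  pos <- sum(estimates > 0) + nz / 2
  neg <- sum(estimates < 0) + nz / 2
  p <- min(1, 2 * min(pos, neg) / n)
  if (min(pos, neg) == 0) attr(p, "p_bound") <- 2 / n
  p
}

#' Fit the component trend model on one no-reuse subset
#'
#' The model contract: fixed effects intercept, time span (years,
#' controls enter at span 0), z-scored covariate (PSR or LUI), and their
#' interaction, on the signed-square-root-transformed response. Moving-
#' average schemes use a linear mixed-effects model (REML) with crossed
#' random intercepts for plot and for the two contributing sampling years
#' of each comparison; the fixed-baseline scheme (unique years per
#' comparison, each plot used once per subset) uses ordinary least
#' squares. Singular fits (zero variance components) are tolerated and
#' flagged, never fatal.
#'
#' @param subset One no-reuse subset of a partitioned pair table (needs
#'   `span`, `cov_z`, `plot_id`, `year_b`, `year_c` and the response
#'   column).
#' @param response Name of the (untransformed) response column.
#' @param scheme `"mixed"` (default for the moving-average schemes) or
#'   `"fixed_baseline"`.
#' @return An object of class `price_fit` with elements `coef` (the four
#'   fixed effects), `singular`, `scheme` and the underlying model.
#' @export
fit_component_model <- function(subset, response,
                                scheme = c("mixed", "fixed_baseline")) {
  scheme <- match.arg(scheme)
  if (nrow(subset) < 4L)
    stop("fit_component_model: fewer rows than fixed-effect parameters",
         call. = FALSE)
  df <- data.frame(y = sqrt_signed(subset[[response]]),
                   span = subset$span, cov_z = subset$cov_z,
                   plot_id = factor(subset$plot_id),
                   year_b = factor(subset$year_b),
                   year_c = factor(subset$year_c))
  if (scheme == "fixed_baseline") {
    m <- stats::lm(y ~ span * cov_z, data = df)
    cf <- stats::coef(m)
    singular <- FALSE
  } else {
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(y ~ span * cov_z + (1 | plot_id) + (1 | year_b) +
                   (1 | year_c),
                 data = df, REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE, check.conv.singular = "ignore",
                   optCtrl = list(xtol_abs = 1e-6, ftol_abs = 1e-6)))))
    cf <- lme4::fixef(m)
    singular <- lme4::isSingular(m)
  }
  cf <- cf[c("(Intercept)", "span", "cov_z", "span:cov_z")]
  names(cf) <- c("intercept", "span", "cov", "span:cov")
  structure(list(coef = cf, singular = singular, scheme = scheme,
                 model = m),
            class = "price_fit")
}

#' Conditional slopes of time at covariate levels
#'
#' slope(x) = beta_span + beta_interaction * z(x), with z() the z-scoring
#' stored on the pair table (covariate scaling is computed once on the
#' full design so slopes are comparable across resampled subsets).
#'
#' @param coefs Named coefficients with entries `span` and `span:cov` (a
#'   `price_fit` object is also accepted).
#' @param levels Raw covariate levels (e.g. PSR 1 and 60, or LUI 0.5 and
#'   3.5).
#' @param cov_mean,cov_sd Scaling constants of the covariate z-score.
#' @return Named vector of slopes of the transformed response per year.
#' @export
conditional_slopes <- function(coefs, levels, cov_mean, cov_sd) {
  if (inherits(coefs, "price_fit")) coefs <- coefs$coef
  if (!all(c("span", "span:cov") %in% names(coefs)))
    stop("conditional_slopes: need span and span:cov coefficients",
         call. = FALSE)
  if (!is.finite(cov_mean) || !is.finite(cov_sd))
    stop("conditional_slopes: unknown covariate scaling", call. = FALSE)
  z <- (levels - cov_mean) / cov_sd
  stats::setNames(coefs[["span"]] + coefs[["span:cov"]] * z,
                  paste0("slope_at_", levels))
}

## Fixed-effect design matrix prediction (population level, RE = 0).
predict_fixed <- function(coefs, span, cov_z) {
  coefs[["intercept"]] + coefs[["span"]] * span + coefs[["cov"]] * cov_z +
    coefs[["span:cov"]] * span * cov_z
}

#' Resampling ensemble of component trend models
#'
#' Draws `n_models` independent no-reuse subsets of the pairwise
#' comparisons, fits the trend model to every requested response on each
#' subset (all responses of one draw share the same subset), and
#' summarizes the ensemble: median point estimates, 2.5/97.5 percentile
#' CIs and empirical two-sided P values for the fixed effects and the
#' conditional slopes of time at the requested covariate levels, plus a
#' prediction grid over (span, covariate level) back-transformed to the
#' original (mg) scale before summarizing. Individual failed fits are
#' redrawn; more than 5% failures abort.
#'
#' @param pairs Partitioned pair table with covariates attached
#'   ([attach_covariates()] stores the scaling).
#' @param responses Response columns to model (default the nine partition
#'   responses).
#' @param n_models Number of subsets/fits (the study design uses 1,000).
#' @param cov_levels Raw covariate levels for conditional slopes and
#'   predictions (e.g. `c(1, 60)` for PSR; the mean-covariate level
#'   `"mean"` is always added for contribution and decline summaries).
#' @param spans Prediction spans (default 0 to the maximum retained span).
#' @param scheme `"mixed"` or `"fixed_baseline"` (see
#'   [fit_component_model()]).
#' @param flip_controls Randomize control direction per subset.
#' @return An object of class `price_ensemble`: `estimates` (term
#'   summaries), `predictions` (grid summaries on the mg scale),
#'   `pred_array` (per-model back-transformed predictions,
#'   models x responses x spans x levels), `vif` (variance inflation
#'   factors of the fixed design on the full pair table), counts of
#'   singular and failed fits, and the covariate scaling.
#' @export
ensemble_inference <- function(pairs, responses = PRICE_RESPONSES,
                               n_models = 1000, cov_levels = NULL,
                               spans = NULL,
                               scheme = c("mixed", "fixed_baseline"),
                               flip_controls = TRUE) {
  scheme <- match.arg(scheme)
  cov_mean <- attr(pairs, "cov_mean")
  cov_sd <- attr(pairs, "cov_sd")
  if (is.null(cov_mean) || is.null(cov_sd))
    stop("ensemble_inference: pairs must carry covariate scaling ",
         "(run attach_covariates first)", call. = FALSE)
  missing_resp <- setdiff(responses, names(pairs))
  if (length(missing_resp))
    stop("ensemble_inference: response column(s) absent: ",
         paste(missing_resp, collapse = ", "), call. = FALSE)
  if (is.null(spans)) spans <- 0:max(pairs$span)
  if (is.null(cov_levels)) cov_levels <- numeric(0)
  level_z <- c((cov_levels - cov_mean) / cov_sd, 0)
  level_names <- c(as.character(cov_levels), "mean")

  vif <- tryCatch(
    variance_inflation(cbind(span = pairs$span, cov_z = pairs$cov_z,
                             `span:cov_z` = pairs$span * pairs$cov_z)),
    error = function(e) NULL)

  matching_sizes <- design_matching_sizes(pairs)
  n_resp <- length(responses)
  term_names <- c("intercept", "span", "cov", "span:cov",
                  if (length(cov_levels))
                    paste0("slope_at_", cov_levels))
  coef_arr <- array(NA_real_, dim = c(n_models, n_resp, length(term_names)),
                    dimnames = list(NULL, responses, term_names))
  pred_arr <- array(NA_real_,
                    dim = c(n_models, n_resp, length(spans),
                            length(level_names)),
                    dimnames = list(NULL, responses, as.character(spans),
                                    level_names))
  grid <- expand.grid(span = spans, z = level_z)
  n_singular <- 0L
  n_failed <- 0L
  max_failed <- ceiling(0.05 * n_models)

  j <- 1L
  while (j <= n_models) {
    sub <- sample_disjoint_subset(pairs, matching_sizes,
                                  flip_controls = flip_controls)
    fit1 <- tryCatch(fit_component_model(sub, responses[1], scheme),
                     error = function(e) e)
    if (inherits(fit1, "error")) {
      n_failed <- n_failed + 1L
      if (n_failed > max_failed)
        stop("ensemble_inference: more than 5% of fits failed (",
             n_failed, " failures); last error: ",
             conditionMessage(fit1), call. = FALSE)
      next
    }
    ok <- TRUE
    for (r in seq_len(n_resp)) {
      if (r == 1L) {
        cf <- fit1$coef
        if (fit1$singular) n_singular <- n_singular + 1L
      } else if (scheme == "fixed_baseline") {
        m <- tryCatch(stats::lm(sqrt_signed(sub[[responses[r]]]) ~
                                  sub$span * sub$cov_z),
                      error = function(e) e)
        if (inherits(m, "error")) { ok <- FALSE; break }
        cf <- stats::setNames(stats::coef(m),
                              c("intercept", "span", "cov", "span:cov"))
      } else {
        m <- tryCatch(suppressMessages(suppressWarnings(
          lme4::refit(fit1$model, sqrt_signed(sub[[responses[r]]])))),
          error = function(e) e)
        if (inherits(m, "error")) { ok <- FALSE; break }
        cf <- stats::setNames(
          lme4::fixef(m)[c("(Intercept)", "span", "cov_z", "span:cov_z")],
          c("intercept", "span", "cov", "span:cov"))
      }
      slopes <- cf[["span"]] + cf[["span:cov"]] * level_z[seq_along(cov_levels)]
      coef_arr[j, r, ] <- c(cf, slopes)
      pred <- predict_fixed(cf, grid$span, grid$z)
      pred_arr[j, r, , ] <- sqrt_signed_inv(pred)
    }
    if (!ok) {
      n_failed <- n_failed + 1L
      if (n_failed > max_failed)
        stop("ensemble_inference: more than 5% of fits failed (",
             n_failed, " failures)", call. = FALSE)
      next
    }
    j <- j + 1L
  }

  estimates <- do.call(rbind, lapply(seq_len(n_resp), function(r) {
    do.call(rbind, lapply(seq_along(term_names), function(t) {
      est <- coef_arr[, r, t]
      p <- empirical_p(est)
      data.frame(component = responses[r], term = term_names[t],
                 median = stats::median(est),
                 ci_low = stats::quantile(est, 0.025, names = FALSE),
                 ci_high = stats::quantile(est, 0.975, names = FALSE),
                 p = as.numeric(p),
                 p_bound = if (!is.null(attr(p, "p_bound")))
                   attr(p, "p_bound") else NA_real_,
                 n_fits = n_models)
    }))
  }))

  predictions <- do.call(rbind, lapply(seq_len(n_resp), function(r) {
    do.call(rbind, lapply(seq_along(level_names), function(l) {
      data.frame(component = responses[r], span = spans,
                 covariate_level = level_names[l],
                 median = apply(pred_arr[, r, , l, drop = FALSE], 3,
                                stats::median),
                 ci_low = apply(pred_arr[, r, , l, drop = FALSE], 3,
                                stats::quantile, 0.025, names = FALSE),
                 ci_high = apply(pred_arr[, r, , l, drop = FALSE], 3,
                                 stats::quantile, 0.975, names = FALSE))
    }))
  }))
  rownames(estimates) <- rownames(predictions) <- NULL

  structure(list(estimates = estimates, predictions = predictions,
                 coef_array = coef_arr, pred_array = pred_arr,
                 spans = spans, cov_levels = cov_levels,
                 cov_mean = cov_mean, cov_sd = cov_sd,
                 responses = responses, scheme = scheme,
                 n_models = n_models, n_singular = n_singular,
                 n_failed = n_failed, vif = vif,
                 subset_size = sum(matching_sizes)),
            class = "price_ensemble")
}

#' @exportS3Method base::print
print.price_ensemble <- function(x, ...) {
  cat("Price-partition resampling ensemble\n")
  cat("  models:", x$n_models, "(", x$n_singular, "singular,",
      x$n_failed, "redrawn );", "subset size:", x$subset_size, "\n")
  cat("  responses:", paste(x$responses, collapse = ", "), "\n")
  if (!is.null(x$vif))
    cat("  VIF:", paste(sprintf("%s=%.2f", names(x$vif), x$vif),
                        collapse = ", "),
        if (any(x$vif >= 2)) " [flag: VIF >= 2]" else "", "\n")
  invisible(x)
}

#' Combined component contributions to total biomass change
#'
#' For each model of the ensemble, the percentage share of the predicted
#' total biomass change at horizon `h` (at the mean covariate) associated
#' with each component grouping: by default richness (`sre_loss +
#' sre_gain`), identity (`sie_loss + sie_gain`), all four turnover
#' components combined, and the abundance change of persisting species
#' (`cde`). Shares are summarized by their median and 95% percentile CI
#' across models; they can exceed 100% or be negative. Models whose
#' predicted total change at `h` is exactly zero are excluded and counted.
#'
#' @param ensemble A `price_ensemble` fitted on (at least) the five
#'   components and `delta_T`.
#' @param horizon Time span h (years) at which to evaluate predictions.
#' @param groups Named list mapping a grouping to component columns.
#' @param level Covariate level of the prediction grid to use (default
#'   `"mean"`).
#' @return Data frame with one row per grouping: median share (%), CI,
#'   number of contributing models and of excluded (zero-denominator)
#'   models.
#' @export
component_contributions <- function(ensemble, horizon,
                                    groups = list(
                                      richness = c("sre_loss", "sre_gain"),
                                      identity = c("sie_loss", "sie_gain"),
                                      turnover = c("sre_loss", "sie_loss",
                                                   "sre_gain", "sie_gain"),
                                      cde = "cde"),
                                    level = "mean") {
  h <- as.character(horizon)
  if (!h %in% dimnames(ensemble$pred_array)[[3]])
    stop("component_contributions: horizon ", horizon,
         " not in the prediction grid", call. = FALSE)
  denom <- ensemble$pred_array[, "delta_T", h, level]
  keep <- denom != 0
  n_excluded <- sum(!keep)
  if (n_excluded)
    message("component_contributions: ", n_excluded,
            " model(s) with zero predicted total change excluded")
  out <- do.call(rbind, lapply(names(groups), function(g) {
    comps <- groups[[g]]
    num <- if (length(comps) == 1) ensemble$pred_array[, comps, h, level]
    else rowSums(ensemble$pred_array[, comps, h, level, drop = FALSE])
    share <- 100 * num[keep] / denom[keep]
    if (!length(share))
      return(data.frame(group = g, horizon = horizon, median = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        n_models = 0L, n_excluded = n_excluded))
    data.frame(group = g, horizon = horizon,
               median = stats::median(share),
               ci_low = stats::quantile(share, 0.025, names = FALSE),
               ci_high = stats::quantile(share, 0.975, names = FALSE),
               n_models = sum(keep), n_excluded = n_excluded)
  }))
  rownames(out) <- NULL
  out
}

#' Percentage biomass decline per year
#'
#' Divides each model's predicted biomass loss at the last timepoint by
#' the average baseline-period biomass, yielding a total percentage loss
#' over the horizon, annualized linearly (total / h; geometric
#' annualization `100 * (1 - (1 - total/100)^(1/h))` available).
#'
#' @param ensemble A `price_ensemble` including `delta_T`.
#' @param baseline_mean Mean per-sample biomass (mg) over the baseline
#'   window (must be > 0).
#' @param horizon Last time span h (years).
#' @param annualization `"linear"` or `"geometric"`.
#' @param level Covariate level of the grid (default `"mean"`).
#' @return One-row data frame with median and CI of the total and yearly
#'   percentage decline.
#' @export
percent_decline <- function(ensemble, baseline_mean, horizon,
                            annualization = c("linear", "geometric"),
                            level = "mean") {
  annualization <- match.arg(annualization)
  if (!is.finite(baseline_mean) || baseline_mean <= 0)
    stop("percent_decline: baseline mean biomass must be > 0",
         call. = FALSE)
  h <- as.character(horizon)
  pred <- ensemble$pred_array[, "delta_T", h, level]
  total <- 100 * abs(pred) / baseline_mean
  yearly <- if (annualization == "linear") total / horizon
  else 100 * (1 - pmax(0, 1 - total / 100)^(1 / horizon))
  data.frame(horizon = horizon, annualization = annualization,
             total_pct = stats::median(total),
             total_ci_low = stats::quantile(total, 0.025, names = FALSE),
             total_ci_high = stats::quantile(total, 0.975, names = FALSE),
             yearly_pct = stats::median(yearly),
             yearly_ci_low = stats::quantile(yearly, 0.025, names = FALSE),
             yearly_ci_high = stats::quantile(yearly, 0.975, names = FALSE))
}
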