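#' Sample coverage of a community sample
#'
#' Estimated proportion of the community's individuals belonging to
#' species represented in the sample, from singleton/doubleton counts.
#' `good_turing`: C = 1 - f1/n. `chao`: C = 1 - (f1/n) * ((n-1) f1 /
#' ((n-1) f1 + 2 f2)), which reduces to Good-Turing when f2 = 0. Values
#' are clamped to \[0, 1\].
#'
#' @param abundances Integer abundance vector of one sample (one entry per
#'   detected species).
#' @param estimator `"chao"` (default) or `"good_turing"`.
#' @return Coverage in \[0, 1\]; `NA` with a warning for an empty sample.
#' @export
#' @examples
#' sample_coverage(c(5, 2, 1, 1, 1))           # n = 10, f1 = 3
#' sample_coverage(c(5, 2, 2, 1), "good_turing")
sample_coverage <- function(abundances,
                            estimator = c("chao", "good_turing")) {
  estimator <- match.arg(estimator)
  abundances <- abundances[abundances > 0]
  n <- sum(abundances)
  if (n == 0) {
    warning("sample_coverage: empty sample, coverage undefined",
            call. = FALSE)
    return(NA_real_)
  }
  f1 <- sum(abundances == 1)
  f2 <- sum(abundances == 2)
  cv <- if (estimator == "good_turing" || (f1 == 0 && f2 == 0)) {
    1 - f1 / n
  } else {
    denom <- (n - 1) * f1 + 2 * f2
    if (denom == 0) 1 - f1 / n
    else 1 - (f1 / n) * ((n - 1) * f1 / denom)
  }
  min(1, max(0, cv))
}

#' Per-sample coverage table for an observation set
#'
#' @param obs Validated observation table (replicate-level samples; the
#'   two seasons of a sample are pooled).
#' @param estimator Passed to [sample_coverage()].
#' @return Data frame `plot_id,year,replicate,n,f1,f2,estimator,coverage`.
#' @export
coverage_table <- function(obs, estimator = c("chao", "good_turing")) {
  estimator <- match.arg(estimator)
  key <- paste(sample_key(obs$plot_id, obs$year, obs$replicate),
               obs$species_id, sep = "\r")
  counts <- rowsum(obs$count, key, reorder = FALSE)
  skey <- sub("\r[^\r]*$", "", rownames(counts))
  rows <- lapply(split(counts[, 1], skey), function(ab) {
    ab <- ab[ab > 0]
    data.frame(n = as.integer(sum(ab)), f1 = as.integer(sum(ab == 1)),
               f2 = as.integer(sum(ab == 2)), estimator = estimator,
               coverage = sample_coverage(ab, estimator))
  })
  ids <- do.call(rbind, strsplit(names(rows), "\r", fixed = TRUE))
  out <- cbind(data.frame(plot_id = ids[, 1], year = as.integer(ids[, 2]),
                          replicate = ids[, 3]),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(out$plot_id, out$year, out$replicate), ]
}

#' Occupancy-based sensitivity filter
#'
#' Restricts the observation table, per year, to species occurring in at
#' least `threshold` of the plots sampled that year (count > 0, replicates
#' and seasons pooled). The plot threshold rounds up: at threshold 0.10
#' with 85 plots a species must occur in >= 9 plots. A species may pass in
#' some years and not others; threshold 0 is the identity filter.
#'
#' @param obs Validated observation table.
#' @param threshold Minimum fraction of plots (the study's sensitivity
#'   analyses use 0.10 and 0.30).
#' @return The filtered observation table; a message reports the number of
#'   retained/removed (year, species) combinations.
#' @export
occupancy_filter <- function(obs, threshold) {
  if (threshold <= 0) return(obs)
  keep <- rep(FALSE, nrow(obs))
  for (yr in unique(obs$year)) {
    in_year <- obs$year == yr
    plots <- unique(obs$plot_id[in_year])
    min_plots <- ceiling(threshold * length(plots))
    occ <- tapply(obs$plot_id[in_year & obs$count > 0],
                  obs$species_id[in_year & obs$count > 0],
                  function(p) length(unique(p)))
    ok_species <- names(occ)[occ >= min_plots]
    keep[in_year] <- obs$species_id[in_year] %in% ok_species
  }
  n_removed <- length(unique(paste(obs$year[!keep], obs$species_id[!keep])))
  n_kept <- length(unique(paste(obs$year[keep], obs$species_id[keep])))
  message("occupancy_filter(", threshold, "): retained ", n_kept,
          " and removed ", n_removed, " (year, species) combinations")
  out <- obs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variance inflation factors of a fixed-effect design
#'
#' VIF_j = 1 / (1 - R^2_j), with R^2_j from regressing column j on the
#' other columns (plus an intercept). Perfectly collinear columns are
#' reported as `Inf` with a warning. The study design requires VIF < 2.
#'
#' @param X Numeric matrix of non-intercept design columns (>= 2 columns,
#'   more rows than columns).
#' @return Named vector of VIFs.
#' @export
variance_inflation <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2)
    stop("variance_inflation: need >= 2 non-intercept columns",
         call. = FALSE)
  if (nrow(X) <= ncol(X))
    stop("variance_inflation: need more rows than columns", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vif <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[, j] - mean(X[, j]))^2)
    if (tss == 0) return(NA_real_)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  if (any(is.infinite(vif)))
    warning("variance_inflation: perfectly collinear column(s): ",
            paste(names(vif)[is.infinite(vif)], collapse = ", "),
            call. = FALSE)
  vif
}
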