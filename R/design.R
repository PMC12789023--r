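#' Rolling 3-year mean of land-use intensity
#'
#' Smooths yearly LUI by averaging the sampling year and the two preceding
#' years; the window is truncated to the years present in the series (a
#' series starting in the requested year returns that year's value).
#'
#' @param lui Covariate table in real-world mode (`plot_id,year,lui`).
#' @param plot_id Plot identifier.
#' @param year Sampling year.
#' @return The windowed mean LUI.
#' @export
lui_rolling_mean <- function(lui, plot_id, year) {
  rows <- lui$plot_id == plot_id & lui$year >= year - 2 & lui$year <= year
  if (!any(rows))
    stop("lui_rolling_mean: no LUI value for plot ", plot_id,
         " in years ", year - 2, "-", year, call. = FALSE)
  mean(lui$lui[rows])
}

#' Enumerate pairwise comparisons under a scheme
#'
#' Builds the ordered within-plot, within-replicate (baseline, comparison)
#' year pairs of the chosen comparison scheme, plus intra-annual control
#' pairs (replicate A vs B in the same plot and year, span 0). Schemes:
#'
#' * `fixed_baseline` — every year against the first sampled year only;
#' * `moving_average` — all ordered year pairs, pooled by time span;
#' * `restricted_moving_average` — moving average restricted to baselines
#'   among the first `baseline_window` sampled years of the design.
#'
#' Time spans realized by fewer than `min_replicates` distinct
#' (baseline year, comparison year) combinations across the design are
#' dropped; this reproduces the maximum replicated spans of designs with
#' year gaps (e.g. 7 years for sampling years
#' {2010, 2012, 2014, 2016, 2017, 2019, 2020} under the restricted scheme,
#' where spans 8-10 occur in a single year combination each).
#'
#' @param samples Data frame of sample keys (`plot_id,year,replicate`), one
#'   row per existing sample.
#' @param scheme Comparison scheme.
#' @param baseline_window Number of earliest sampled years usable as
#'   baselines under the restricted scheme (`Inf` recovers the plain
#'   moving average).
#' @param min_replicates Minimum distinct year combinations per retained
#'   span.
#' @param include_controls Append span-0 control pairs (set `FALSE` for
#'   the no-controls sensitivity analysis).
#' @return Pair table with columns
#'   `plot_id,replicate_b,replicate_c,year_b,year_c,span,scheme`.
#' @export
enumerate_pairs <- function(samples,
                            scheme = c("restricted_moving_average",
                                       "moving_average", "fixed_baseline"),
                            baseline_window = 5, min_replicates = 2,
                            include_controls = TRUE) {
  scheme <- match.arg(scheme)
  samples <- unique(samples[c("plot_id", "year", "replicate")])
  samples$year <- as.integer(samples$year)
  all_years <- sort(unique(samples$year))
  first_years <- if (is.finite(baseline_window))
    utils::head(all_years, baseline_window) else all_years

  chains <- split(samples$year,
                  paste(samples$plot_id, samples$replicate, sep = "\r"))
  temporal <- lapply(names(chains), function(k) {
    yrs <- sort(unique(chains[[k]]))
    if (length(yrs) < 2) return(NULL)
    pp <- strsplit(k, "\r", fixed = TRUE)[[1]]
    grid <- expand.grid(year_b = yrs, year_c = yrs)
    grid <- grid[grid$year_b < grid$year_c, , drop = FALSE]
    grid <- switch(scheme,
      fixed_baseline = grid[grid$year_b == yrs[1], , drop = FALSE],
      moving_average = grid,
      restricted_moving_average =
        grid[grid$year_b %in% first_years, , drop = FALSE])
    if (nrow(grid) == 0) return(NULL)
    data.frame(plot_id = pp[1], replicate_b = pp[2], replicate_c = pp[2],
               year_b = grid$year_b, year_c = grid$year_c)
  })
  temporal <- do.call(rbind, temporal)

  if (!is.null(temporal) && nrow(temporal)) {
    temporal$span <- temporal$year_c - temporal$year_b
    temporal$scheme <- scheme
    ## span support = distinct year combinations, pooled over plots
    combo <- unique(temporal[c("year_b", "year_c", "span")])
    support <- table(combo$span)
    keep <- as.integer(names(support)[support >= min_replicates])
    temporal <- temporal[temporal$span %in% keep, , drop = FALSE]
  } else {
    temporal <- NULL
  }

  controls <- NULL
  if (include_controls) {
    py <- split(samples$replicate, paste(samples$plot_id, samples$year,
                                         sep = "\r"))
    ctl <- lapply(names(py), function(k) {
      reps <- sort(unique(py[[k]]))
      if (length(reps) < 2) return(NULL)
      pp <- strsplit(k, "\r", fixed = TRUE)[[1]]
      cmb <- utils::combn(reps, 2)
      data.frame(plot_id = pp[1], replicate_b = cmb[1, ],
                 replicate_c = cmb[2, ],
                 year_b = as.integer(pp[2]), year_c = as.integer(pp[2]),
                 span = 0L, scheme = "control")
    })
    controls <- do.call(rbind, ctl)
  }

  out <- rbind(temporal, controls)
  if (is.null(out))
    out <- data.frame(plot_id = character(), replicate_b = character(),
                      replicate_c = character(), year_b = integer(),
                      year_c = integer(), span = integer(),
                      scheme = character())
  out <- out[order(out$plot_id, out$span, out$year_b, out$replicate_b), ]
  rownames(out) <- NULL
  out
}

#' Attach the comparison-level covariate and its z-score
#'
#' Experiment mode attaches the plot's sown plant species richness (PSR);
#' real-world mode attaches the mean of the two endpoint rolling-mean LUI
#' values (LUI is averaged within each comparison). The covariate is
#' z-scored over the full pair table and the scaling constants are stored
#' as attributes `cov_mean` / `cov_sd` so that conditional slopes and
#' predictions at raw covariate levels stay comparable across resampled
#' subsets.
#'
#' @param pairs Pair table from [enumerate_pairs()].
#' @param covariates Covariate table from [read_covariates()] (or any data
#'   frame with the same columns; the mode is re-detected from them).
#' @return `pairs` with columns `covariate` and `cov_z` appended.
#' @export
attach_covariates <- function(pairs, covariates) {
  covariates <- validate_covariates(covariates)
  mode <- attr(covariates, "covariate_mode")
  if (mode == "experiment") {
    idx <- match(pairs$plot_id, covariates$plot_id)
    if (anyNA(idx))
      stop("attach_covariates: no PSR for plot(s): ",
           paste(unique(pairs$plot_id[is.na(idx)]), collapse = ", "),
           call. = FALSE)
    pairs$covariate <- covariates$psr[idx]
  } else {
    roll <- function(p, y) lui_rolling_mean(covariates, p, y)
    key_b <- paste(pairs$plot_id, pairs$year_b)
    key_c <- paste(pairs$plot_id, pairs$year_c)
    uk <- unique(c(key_b, key_c))
    vals <- vapply(strsplit(uk, " ", fixed = TRUE),
                   function(x) roll(x[1], as.integer(x[2])), numeric(1))
    names(vals) <- uk
    pairs$covariate <- (vals[key_b] + vals[key_c]) / 2
  }
  mu <- mean(pairs$covariate)
  sdv <- stats::sd(pairs$covariate)
  if (!is.finite(sdv) || sdv == 0)
    stop("attach_covariates: covariate has zero variance, cannot z-score",
         call. = FALSE)
  pairs$cov_z <- (pairs$covariate - mu) / sdv
  attr(pairs, "cov_mean") <- mu
  attr(pairs, "cov_sd") <- sdv
  attr(pairs, "covariate_mode") <- mode
  rownames(pairs) <- NULL
  pairs
}

## ---- no-reuse subset sampling -------------------------------------------

## Vertex labels of the one or two sampling events a pair occupies.
## A temporal pair occupies its replicate's event in both years; a control
## occupies both replicate events of its plot/year.
pair_vertices <- function(pairs) {
  lapply(seq_len(nrow(pairs)), function(i) {
    if (pairs$scheme[i] == "control")
      c(paste(pairs$year_b[i], pairs$replicate_b[i]),
        paste(pairs$year_b[i], pairs$replicate_c[i]))
    else
      c(paste(pairs$year_b[i], pairs$replicate_b[i]),
        paste(pairs$year_c[i], pairs$replicate_c[i]))
  })
}

## Exact maximum matching size by branch-and-bound on the (small)
## per-plot event graph.
max_matching_size <- function(edges) {
  if (!length(edges)) return(0L)
  verts <- sort(unique(unlist(edges)))
  e1 <- match(vapply(edges, `[`, "", 1L), verts)
  e2 <- match(vapply(edges, `[`, "", 2L), verts)
  n <- length(verts)
  best <- 0L
  recurse <- function(used, avail, size) {
    if (size + length(avail) <= best) return(invisible())
    if (!length(avail)) {
      if (size > best) best <<- size
      return(invisible())
    }
    ## branch on the lowest free vertex with an available edge
    v <- min(e1[avail], e2[avail])
    at_v <- avail[e1[avail] == v | e2[avail] == v]
    rest <- setdiff(avail, at_v)
    for (e in at_v) {
      u <- if (e1[e] == v) e2[e] else e1[e]
      keep <- rest[e1[rest] != u & e2[rest] != u]
      recurse(c(used, e), keep, size + 1L)
    }
    ## v left unmatched
    recurse(used, rest, size)
    invisible()
  }
  recurse(integer(0), seq_along(edges), 0L)
  best
}

#' Per-plot maximum matching sizes of a comparison design
#'
#' For each plot, the maximum number of pairwise comparisons that can be
#' drawn without using any sampling event (plot, year, replicate) in more
#' than one comparison. Controls occupy both replicate events of their
#' plot/year. The subset size of [sample_disjoint_subset()] is the sum of
#' these per-plot sizes and is a design invariant.
#'
#' @param pairs Pair table.
#' @return Named integer vector of matching sizes per plot.
#' @export
design_matching_sizes <- function(pairs) {
  vl <- pair_vertices(pairs)
  by_plot <- split(seq_len(nrow(pairs)), pairs$plot_id)
  cache <- new.env(parent = emptyenv())
  vapply(by_plot, function(idx) {
    edges <- vl[idx]
    key <- paste(sort(vapply(edges, paste, "", collapse = "|")),
                 collapse = ";")
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- max_matching_size(edges)
    cache[[key]] <- m
    m
  }, integer(1))
}

#' Draw one no-reuse subset of pairwise comparisons
#'
#' Samples a random subset of the enumerated comparisons in which no
#' sampling event participates more than once, of the maximum possible
#' size (per-plot maximum matching). The sampler shuffles each plot's
#' pairs uniformly and accepts greedily, retrying up to `max_tries`
#' shuffles until the plot's exact maximum matching size is reached.
#' Accepted controls are flipped to the reverse direction (B vs A) with
#' probability 1/2; if partition response columns are present they are
#' flipped accordingly (role swap negates `delta_T` and `cde` and swaps
#' loss and gain terms with sign change).
#'
#' @param pairs Pair table (optionally already partitioned and with
#'   covariates).
#' @param matching_sizes Precomputed [design_matching_sizes()] (computed on
#'   the fly when `NULL`; precompute for repeated ensemble draws).
#' @param max_tries Shuffle restarts per plot.
#' @param flip_controls Randomize control direction.
#' @return Subset of `pairs` rows (controls possibly direction-flipped,
#'   column `flipped` added).
#' @export
sample_disjoint_subset <- function(pairs, matching_sizes = NULL,
                                   max_tries = 50, flip_controls = TRUE) {
  if (is.null(matching_sizes)) matching_sizes <- design_matching_sizes(pairs)
  ## integer vertex ids: one per (plot, year, replicate) sampling event
  is_ctl <- pairs$scheme == "control"
  v1_key <- paste(pairs$plot_id, pairs$year_b, pairs$replicate_b)
  v2_key <- ifelse(is_ctl,
                   paste(pairs$plot_id, pairs$year_b, pairs$replicate_c),
                   paste(pairs$plot_id, pairs$year_c, pairs$replicate_c))
  verts <- unique(c(v1_key, v2_key))
  v1 <- match(v1_key, verts)
  v2 <- match(v2_key, verts)
  occupied <- logical(length(verts))
  by_plot <- split(seq_len(nrow(pairs)), pairs$plot_id)
  chosen <- integer(0)
  for (plot in names(by_plot)) {
    idx <- by_plot[[plot]]
    target <- matching_sizes[[plot]]
    best <- integer(0)
    for (try in seq_len(max_tries)) {
      ord <- sample(idx)
      acc <- integer(length(idx))
      n_acc <- 0L
      for (e in ord) {
        if (!occupied[v1[e]] && !occupied[v2[e]]) {
          n_acc <- n_acc + 1L
          acc[n_acc] <- e
          occupied[v1[e]] <- TRUE
          occupied[v2[e]] <- TRUE
        }
      }
      acc <- acc[seq_len(n_acc)]
      occupied[v1[acc]] <- FALSE
      occupied[v2[acc]] <- FALSE
      if (n_acc > length(best)) best <- acc
      if (length(best) >= target) break
    }
    chosen <- c(chosen, best)
  }
  out <- pairs[chosen, , drop = FALSE]
  out$flipped <- FALSE
  if (flip_controls && any(out$scheme == "control")) {
    ctl <- which(out$scheme == "control")
    flip <- ctl[stats::runif(length(ctl)) < 0.5]
    if (length(flip)) out <- flip_pairs(out, flip)
  }
  rownames(out) <- NULL
  out
}

## Reverse the (baseline, comparison) roles of the given rows, including
## any partition response columns present.
flip_pairs <- function(pairs, rows) {
  sw <- function(a, b) {
    tmp <- pairs[[a]][rows]
    pairs[[a]][rows] <<- pairs[[b]][rows]
    pairs[[b]][rows] <<- tmp
  }
  sw("replicate_b", "replicate_c")
  sw("year_b", "year_c")
  pairs$flipped[rows] <- TRUE
  if ("sre_loss" %in% names(pairs)) {
    old <- pairs[rows, , drop = FALSE]
    pairs$sre_loss[rows] <- -old$sre_gain
    pairs$sie_loss[rows] <- -old$sie_gain
    pairs$sre_gain[rows] <- -old$sre_loss
    pairs$sie_gain[rows] <- -old$sie_loss
    pairs$cde[rows] <- -old$cde
    pairs$delta_T[rows] <- -old$delta_T
    pairs$sp_lost[rows] <- -old$sp_gained
    pairs$sp_gained[rows] <- -old$sp_lost
    pairs$sp_net[rows] <- -old$sp_net
    if ("s_baseline" %in% names(pairs)) {
      sw("s_baseline", "s_comparison")
      sw("T_baseline", "T_comparison")
    }
  }
  pairs
}
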