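#' Split one pooled sample into two within-year replicates
#'
#' Emulates a two-replicate design from a single pooled field sample: a
#' Poisson-distributed number of individuals (mean N/2, truncated to
#' \[0, N\]) is drawn uniformly without replacement at the individual level
#' to form replicate A; the remaining individuals form replicate B.
#' Per-species counts are conserved exactly (A + B = input).
#'
#' Uses the current RNG state; seed with [set.seed()] for reproducibility.
#'
#' @param obs Observation rows of a single sampling event (one plot, year
#'   and season; any replicate label).
#' @return A list with observation tables `A` and `B` (replicate column
#'   relabelled; zero-count rows dropped).
#' @export
split_sample <- function(obs) {
  n_total <- sum(obs$count)
  if (n_total == 0)
    return(list(A = relabel_replicate(obs[0, ], "A"),
                B = relabel_replicate(obs[0, ], "B")))
  n_a <- min(stats::rpois(1, n_total / 2), n_total)
  individuals <- rep(seq_len(nrow(obs)), obs$count)
  a_idx <- if (n_a > 0) sample(individuals, n_a) else integer(0)
  counts_a <- tabulate(a_idx, nbins = nrow(obs))
  a <- obs
  a$count <- counts_a
  b <- obs
  b$count <- obs$count - counts_a
  list(A = relabel_replicate(a[a$count > 0, , drop = FALSE], "A"),
       B = relabel_replicate(b[b$count > 0, , drop = FALSE], "B"))
}

#' Bootstrap an artificial replicate from a pooled sample
#'
#' For samplings where a physical second replicate is unavailable: draws a
#' Poisson-distributed number of individuals (mean `mean_n`, default the
#' full sample size N) with replacement from the sample. The output
#' species set is always a subset of the input's.
#'
#' @param obs Observation rows of a single sampling event.
#' @param mean_n Mean of the Poisson draw size: `"N"` (full-effort
#'   resample, default) or `"N/2"`.
#' @param label Replicate label for the output (default `"B"`).
#' @return An observation table (zero-count rows dropped).
#' @export
bootstrap_replicate <- function(obs, mean_n = c("N", "N/2"), label = "B") {
  mean_n <- match.arg(mean_n)
  n_total <- sum(obs$count)
  if (n_total == 0) {
    message("bootstrap_replicate: empty input sample, empty replicate")
    return(relabel_replicate(obs[0, ], label))
  }
  mu <- if (mean_n == "N") n_total else n_total / 2
  n_draw <- stats::rpois(1, mu)
  individuals <- rep(seq_len(nrow(obs)), obs$count)
  drawn <- if (n_draw > 0)
    sample(individuals, n_draw, replace = TRUE) else integer(0)
  out <- obs
  out$count <- tabulate(drawn, nbins = nrow(obs))
  relabel_replicate(out[out$count > 0, , drop = FALSE], label)
}

#' Synthesize replicates for every sampling event of a table
#'
#' Applies [split_sample()] per (plot, year, season) event to a table of
#' pooled samples, producing a two-replicate table.
#'
#' @param obs Observation table whose samples are pooled (single replicate
#'   label per event).
#' @return Observation table with replicates `"A"` and `"B"`.
#' @export
synthesize_replicates <- function(obs) {
  key <- paste(obs$plot_id, obs$year, obs$season, sep = "\r")
  parts <- lapply(split(obs, key), function(ev) {
    sp <- split_sample(ev)
    rbind(sp$A, sp$B)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

relabel_replicate <- function(obs, label) {
  if (nrow(obs)) obs$replicate <- label
  else if ("replicate" %in% names(obs)) obs$replicate <- character(0)
  obs
}
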