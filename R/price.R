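## Names of the nine response columns produced by partition_batch():
## the five Price components, total function change, and the three
## richness bookkeeping deltas.
PRICE_COMPONENTS <- c("sre_loss", "sie_loss", "sre_gain", "sie_gain", "cde")
PRICE_RESPONSES <- c(PRICE_COMPONENTS, "delta_T",
                     "sp_lost", "sp_gained", "sp_net")

#' Five-part ecological Price partition of function change
#'
#' Decomposes the change in total community function (biomass) between a
#' baseline and a comparison community into five additive components.
#' With s, s' the two richnesses, s_c the shared richness, T, T' the
#' totals, zbar = T/s, zbar' = T'/s' and C the shared species set:
#'
#' * `sre_loss  = -(s - s_c) * zbar` — expected loss if every lost species
#'   had the baseline's average per-species biomass (species richness loss;
#'   always <= 0),
#' * `sie_loss  = sum_C z_i - s_c * zbar` — deviation of the observed loss
#'   from that expectation (species identity loss),
#' * `sre_gain  = (s' - s_c) * zbar'` — expected gain at the comparison's
#'   average (species richness gain; always >= 0),
#' * `sie_gain  = s_c * zbar' - sum_C z'_i` — deviation of the observed
#'   gain from that expectation (species identity gain),
#' * `cde       = sum_C (z'_i - z_i)` — function change of persisting
#'   species (with constant per-species body mass this is purely abundance
#'   change).
#'
#' The five components sum to `delta_T = T' - T` exactly. If one side is
#' empty its mean is undefined and the corresponding richness/identity
#' terms are zero, so all change loads on the other side's terms; two
#' empty communities give an all-zero partition.
#'
#' @param baseline,comparison Named numeric vectors of per-species function
#'   contributions z_i (names are species ids; only species with positive
#'   abundance appear).
#' @return A one-row data frame with the five components, `delta_T`,
#'   richness bookkeeping (`s_baseline`, `s_comparison`, `s_shared`,
#'   `sp_lost`, `sp_gained`, `sp_net`) and totals `T_baseline`,
#'   `T_comparison`, all in mg.
#' @export
#' @examples
#' b <- c(A = 4, B = 2, C = 6)
#' co <- c(A = 3, B = 2, D = 1)
#' price_partition(b, co)  # components -4, -2, +2, -1, -1; delta_T = -6
price_partition <- function(baseline, comparison) {
  s <- length(baseline)
  s2 <- length(comparison)
  shared <- intersect(names(baseline), names(comparison))
  s_c <- length(shared)
  T1 <- sum(baseline)
  T2 <- sum(comparison)
  zbar1 <- if (s > 0) T1 / s else 0
  zbar2 <- if (s2 > 0) T2 / s2 else 0
  sum_zb <- sum(baseline[shared])
  sum_zc <- sum(comparison[shared])
  data.frame(
    s_baseline = s, s_comparison = s2, s_shared = s_c,
    T_baseline = T1, T_comparison = T2,
    sre_loss = -(s - s_c) * zbar1,
    sie_loss = sum_zb - s_c * zbar1,
    sre_gain = (s2 - s_c) * zbar2,
    sie_gain = s_c * zbar2 - sum_zc,
    cde = sum_zc - sum_zb,
    delta_T = T2 - T1,
    sp_lost = -(s - s_c),
    sp_gained = s2 - s_c,
    sp_net = s2 - s
  )
}

#' Partition a batch of comparison pairs
#'
#' Computes the Price partition for every row of a comparison-pair table
#' against a function-vector table, returning the pair bookkeeping plus the
#' nine response columns (five components, `delta_T`, species lost/gained/
#' net).
#'
#' @param pairs Pair table from [enumerate_pairs()] (possibly with
#'   covariates attached); both endpoint samples must resolve in `fv`,
#'   except that samples with no species resolve to valid empty vectors
#'   when `allow_empty = TRUE`.
#' @param fv Function-vector table from [build_function_vectors()].
#' @param allow_empty Treat unresolved sample keys as empty communities
#'   (an empty sample has no rows in `fv` by construction). Default `TRUE`
#'   when `fv` carries sample keys for them is impossible to distinguish;
#'   set `FALSE` to error on unresolved keys instead.
#' @return `pairs` with the partition columns appended, one row per pair.
#' @export
partition_batch <- function(pairs, fv, allow_empty = TRUE) {
  part_cols <- c("s_baseline", "s_comparison", "s_shared", "T_baseline",
                 "T_comparison", PRICE_RESPONSES)
  if (nrow(pairs) == 0) {
    empty <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(part_cols)), part_cols))
    return(cbind(pairs, empty))
  }
  kb <- sample_key(pairs$plot_id, pairs$year_b, pairs$replicate_b)
  kc <- sample_key(pairs$plot_id, pairs$year_c, pairs$replicate_c)
  fvl <- fv_as_list(fv, keys = unique(c(kb, kc)))
  if (!allow_empty) {
    present <- unique(sample_key(fv$plot_id, fv$year, fv$replicate))
    bad <- setdiff(unique(c(kb, kc)), present)
    if (length(bad))
      stop("partition_batch: unresolved sample key(s): ",
           paste(gsub("\r", "/", utils::head(bad, 5)), collapse = "; "),
           call. = FALSE)
  }
  ## vectorized core: per-pair set statistics into a preallocated matrix
  n <- nrow(pairs)
  stats_mat <- matrix(0, n, 7,
                      dimnames = list(NULL, c("s", "s2", "s_c", "T1", "T2",
                                              "sum_zb", "sum_zc")))
  for (i in seq_len(n)) {
    b <- fvl[[kb[i]]]
    co <- fvl[[kc[i]]]
    m <- match(names(b), names(co))
    hit <- !is.na(m)
    stats_mat[i, ] <- c(length(b), length(co), sum(hit), sum(b), sum(co),
                        sum(b[hit]), sum(co[m[hit]]))
  }
  s <- stats_mat[, "s"]; s2 <- stats_mat[, "s2"]; s_c <- stats_mat[, "s_c"]
  T1 <- stats_mat[, "T1"]; T2 <- stats_mat[, "T2"]
  zbar1 <- ifelse(s > 0, T1 / s, 0)
  zbar2 <- ifelse(s2 > 0, T2 / s2, 0)
  part <- data.frame(
    s_baseline = as.integer(s), s_comparison = as.integer(s2),
    s_shared = as.integer(s_c), T_baseline = T1, T_comparison = T2,
    sre_loss = -(s - s_c) * zbar1,
    sie_loss = stats_mat[, "sum_zb"] - s_c * zbar1,
    sre_gain = (s2 - s_c) * zbar2,
    sie_gain = s_c * zbar2 - stats_mat[, "sum_zc"],
    cde = stats_mat[, "sum_zc"] - stats_mat[, "sum_zb"],
    delta_T = T2 - T1,
    sp_lost = as.integer(-(s - s_c)),
    sp_gained = as.integer(s2 - s_c),
    sp_net = as.integer(s2 - s))
  out <- cbind(pairs, part)
  for (a in c("cov_mean", "cov_sd", "covariate_mode"))
    attr(out, a) <- attr(pairs, a)
  out
}
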