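## Shared fixtures and independent oracles. The oracles deliberately use
## explicit set operations and loops so they share no code path with the
## package implementation.

tiny_allometry <- function() {
  data.frame(taxon_group = c("Coleoptera", "Hemiptera", "Araneae-hunting"),
             a = c(0.05, 0.1, 1), b = c(2.5, 2, 1))
}

## One observation row builder with sensible defaults.
obs_row <- function(plot = "p1", year = 2010, season = "spring",
                    replicate = "A", species = "sp1",
                    taxon = "Coleoptera", guild = "herbivore",
                    count = 1, len = 4) {
  data.frame(plot_id = plot, region = "main", year = year, season = season,
             replicate = replicate, species_id = species,
             taxon_group = taxon, guild = guild,
             count = as.integer(count), body_length_mm = len)
}

## Brute-force Price partition from raw set operations: lost, gained and
## shared species are enumerated explicitly and every term is accumulated
## in a loop from its own definition (expected change at the community
## mean; deviation of observed from expected; per-species change of
## persisters).
oracle_price <- function(b, co) {
  lost <- setdiff(names(b), names(co))
  gained <- setdiff(names(co), names(b))
  shared <- intersect(names(b), names(co))
  zbar <- if (length(b)) sum(b) / length(b) else 0
  zbar2 <- if (length(co)) sum(co) / length(co) else 0
  sre_loss <- 0
  for (sp in lost) sre_loss <- sre_loss - zbar
  obs_loss <- 0
  for (sp in lost) obs_loss <- obs_loss - b[[sp]]
  sie_loss <- obs_loss - sre_loss
  sre_gain <- 0
  for (sp in gained) sre_gain <- sre_gain + zbar2
  obs_gain <- 0
  for (sp in gained) obs_gain <- obs_gain + co[[sp]]
  sie_gain <- obs_gain - sre_gain
  cde <- 0
  for (sp in shared) cde <- cde + (co[[sp]] - b[[sp]])
  c(sre_loss = sre_loss, sie_loss = sie_loss, sre_gain = sre_gain,
    sie_gain = sie_gain, cde = cde, delta_T = sum(co) - sum(b))
}

## Random function vector over a species universe.
random_fv <- function(n_universe = 12, p_present = 0.6, max_z = 10) {
  universe <- paste0("s", seq_len(n_universe))
  present <- universe[runif(n_universe) < p_present]
  stats::setNames(runif(length(present), 0.01, max_z), present)
}

## Exhaustive maximum matching on a pair table: every subset of pairs is
## explored via depth-first search over event bitmasks (events =
## (plot, year, replicate); controls occupy both replicate events).
brute_matching_size <- function(pairs) {
  is_ctl <- pairs$scheme == "control"
  v1 <- paste(pairs$plot_id, pairs$year_b, pairs$replicate_b)
  v2 <- ifelse(is_ctl, paste(pairs$plot_id, pairs$year_b, pairs$replicate_c),
               paste(pairs$plot_id, pairs$year_c, pairs$replicate_c))
  verts <- unique(c(v1, v2))
  stopifnot(length(verts) <= 30)
  masks <- bitwOr(bitwShiftL(1L, match(v1, verts) - 1L),
                  bitwShiftL(1L, match(v2, verts) - 1L))
  n <- length(masks)
  dfs <- function(i, used) {
    if (i > n) return(0L)
    best <- dfs(i + 1L, used)
    if (bitwAnd(masks[i], used) == 0L)
      best <- max(best, 1L + dfs(i + 1L, bitwOr(masks[i], used)))
    best
  }
  dfs(1L, 0L)
}

## Events used by a subset, for reuse checks.
subset_events <- function(sub) {
  is_ctl <- sub$scheme == "control"
  c(paste(sub$plot_id, sub$year_b, sub$replicate_b),
    ifelse(is_ctl, paste(sub$plot_id, sub$year_b, sub$replicate_c),
           paste(sub$plot_id, sub$year_c, sub$replicate_c)))
}

## Small sample-key frame for design tests.
key_frame <- function(plots, years, replicates = c("A", "B")) {
  expand.grid(plot_id = plots, year = years, replicate = replicates,
              stringsAsFactors = FALSE)
}
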