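#' Individual dry mass from body length
#'
#' Applies the taxon-specific allometric power law m = a * L^b (L in mm,
#' m in mg). Vectorized over observations.
#'
#' @param length_mm Body length(s) in mm, > 0.
#' @param taxon_group Taxon group key(s) into `allometry`.
#' @param allometry Allometric coefficient table (see [read_allometry()]).
#' @return Individual dry mass in mg.
#' @export
#' @examples
#' allom <- data.frame(taxon_group = "Coleoptera", a = 0.05, b = 2.5)
#' individual_dry_mass(4, "Coleoptera", allom)  # 0.05 * 4^2.5 = 1.6
individual_dry_mass <- function(length_mm, taxon_group, allometry) {
  if (any(!is.finite(length_mm) | length_mm <= 0))
    stop("individual_dry_mass: body length must be > 0", call. = FALSE)
  idx <- match(taxon_group, allometry$taxon_group)
  if (anyNA(idx))
    stop("individual_dry_mass: unknown taxon group(s): ",
         paste(unique(taxon_group[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  allometry$a[idx] * length_mm^allometry$b[idx]
}

#' Build per-sample community function vectors
#'
#' Pools the two seasonal samplings of each (plot, year, replicate) sample,
#' optionally restricts to a trophic guild subset, and attaches each
#' species' biomass contribution z_i: abundance x individual mass in
#' `total_biomass` mode, or the individual mass alone in
#' `mean_individual_biomass` mode (abundance is carried but not
#' multiplied, removing abundance effects from the turnover components).
#'
#' @param obs Validated observation table.
#' @param allometry Allometric coefficient table.
#' @param mode `"total_biomass"` or `"mean_individual_biomass"`.
#' @param guild_filter Optional character vector of guilds to retain.
#' @return A data frame with columns
#'   `plot_id,year,replicate,species_id,abundance,z_mg` (one row per
#'   species per sample; species with zero pooled abundance are absent)
#'   and attribute `mode`. An empty sample is a valid empty vector.
#' @export
build_function_vectors <- function(obs, allometry,
                                   mode = c("total_biomass",
                                            "mean_individual_biomass"),
                                   guild_filter = NULL) {
  mode <- match.arg(mode)
  if (!is.null(guild_filter))
    obs <- obs[obs$guild %in% guild_filter, , drop = FALSE]
  obs <- obs[obs$count > 0, , drop = FALSE]
  if (nrow(obs) == 0) {
    out <- data.frame(plot_id = character(), year = integer(),
                      replicate = character(), species_id = character(),
                      abundance = integer(), z_mg = numeric())
    attr(out, "mode") <- mode
    return(out)
  }
  key <- paste(sample_key(obs$plot_id, obs$year, obs$replicate),
               obs$species_id, sep = "\r")
  counts <- rowsum(obs$count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- obs[first, c("plot_id", "year", "replicate", "species_id",
                      "taxon_group", "body_length_mm"), drop = FALSE]
  out$abundance <- as.integer(counts[match(key[first], rownames(counts)), 1])
  m <- individual_dry_mass(out$body_length_mm, out$taxon_group, allometry)
  out$z_mg <- if (mode == "total_biomass") out$abundance * m else m
  out <- out[c("plot_id", "year", "replicate", "species_id", "abundance",
               "z_mg")]
  out <- out[order(out$plot_id, out$year, out$replicate, out$species_id), ]
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  out
}

#' Summarize function vectors per sample
#'
#' @param fv Function-vector table from [build_function_vectors()].
#' @return One row per sample with total function T (mg), richness s and
#'   mean per-species function zbar = T/s (`NA` for empty samples).
#' @export
function_vector_summary <- function(fv) {
  if (nrow(fv) == 0)
    return(data.frame(plot_id = character(), year = integer(),
                      replicate = character(), T_mg = numeric(),
                      s = integer(), zbar_mg = numeric()))
  key <- sample_key(fv$plot_id, fv$year, fv$replicate)
  first <- !duplicated(key)
  out <- fv[first, c("plot_id", "year", "replicate")]
  totals <- rowsum(fv$z_mg, key, reorder = FALSE)
  rich <- rowsum(rep(1L, nrow(fv)), key, reorder = FALSE)
  out$T_mg <- totals[match(key[first], rownames(totals)), 1]
  out$s <- as.integer(rich[match(key[first], rownames(rich)), 1])
  out$zbar_mg <- ifelse(out$s > 0, out$T_mg / out$s, NA_real_)
  rownames(out) <- NULL
  out
}

## Split a function-vector table into a list of named z vectors keyed by
## sample, for fast pairwise partitioning. Samples listed in `keys` but
## absent from `fv` become empty vectors.
fv_as_list <- function(fv, keys = NULL) {
  key <- sample_key(fv$plot_id, fv$year, fv$replicate)
  z <- fv$z_mg
  names(z) <- fv$species_id
  out <- split(z, key)
  if (!is.null(keys)) {
    miss <- setdiff(keys, names(out))
    if (length(miss)) {
      empties <- stats::setNames(
        rep(list(stats::setNames(numeric(0), character(0))), length(miss)),
        miss)
      out <- c(out, empties)
    }
  }
  out
}
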