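#' @keywords internal
"_PACKAGE"

## Column contracts shared by readers, writers and the generator.
OBS_COLS <- c("plot_id", "region", "year", "season", "replicate",
              "species_id", "taxon_group", "guild", "count",
              "body_length_mm")
ALLOM_COLS <- c("taxon_group", "a", "b")
GUILDS <- c("herbivore", "predator", "other")

#' Read an allometric coefficient table
#'
#' The table maps a taxon group (e.g. Coleoptera, Araneae-hunting) to the
#' coefficients of the length-mass power law m = a * L^b, with L the body
#' length in mm and m the individual dry mass in mg. Coefficient values are
#' user-supplied (taken from the literature for real data); the package
#' ships a synthetic placeholder table in `inst/extdata`.
#'
#' @param path Path to a CSV with columns `taxon_group,a,b`.
#' @return A data frame with one row per taxon group.
#' @export
read_allometry <- function(path) {
  check_file(path, "allometry")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(tab, ALLOM_COLS, "allometry")
  validate_allometry(tab)
}

#' @rdname read_allometry
#' @param tab A data frame with columns `taxon_group,a,b`.
#' @export
validate_allometry <- function(tab) {
  check_columns(tab, ALLOM_COLS, "allometry")
  if (anyDuplicated(tab$taxon_group))
    stop("allometry: duplicated taxon_group entries", call. = FALSE)
  if (!is.numeric(tab$a) || !is.numeric(tab$b))
    stop("allometry: a and b must be numeric", call. = FALSE)
  if (any(tab$a <= 0))
    stop("allometry: intercept a must be > 0", call. = FALSE)
  tab[ALLOM_COLS]
}

#' Read and validate a species observation table
#'
#' One row is one species count (with its constant body length) at one
#' (plot, year, season, replicate) sampling. Duplicate rows for the same
#' sampling and species are summed with a warning; inconsistent species
#' attributes (body length, taxon group or guild varying within a species)
#' are an error, as are negative counts, non-positive lengths and taxon
#' groups missing from the allometric table.
#'
#' @param path Path to a CSV with columns
#'   `plot_id,region,year,season,replicate,species_id,taxon_group,guild,count,body_length_mm`.
#' @param allometry Allometric table covering every taxon group present, or
#'   `NULL` to skip the coverage check.
#' @return A validated data frame with the observation columns.
#' @export
read_observations <- function(path, allometry = NULL) {
  check_file(path, "observations")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(plot_id = "character",
                                        region = "character",
                                        season = "character",
                                        replicate = "character",
                                        species_id = "character",
                                        taxon_group = "character",
                                        guild = "character"))
  validate_observations(tab, allometry)
}

#' @rdname read_observations
#' @param obs A data frame with the observation columns.
#' @export
validate_observations <- function(obs, allometry = NULL) {
  check_columns(obs, OBS_COLS, "observations")
  obs <- obs[OBS_COLS]
  if (nrow(obs) == 0) return(obs)

  if (!is.numeric(obs$count))
    stop("observations: count must be numeric integer, not ",
         class(obs$count)[1], call. = FALSE)
  bad <- which(obs$count < 0 | obs$count != round(obs$count))
  if (length(bad))
    stop("observations: invalid count at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  obs$count <- as.integer(round(obs$count))
  bad <- which(!is.finite(obs$body_length_mm) | obs$body_length_mm <= 0)
  if (length(bad))
    stop("observations: non-positive body_length_mm at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  if (!all(obs$guild %in% GUILDS))
    stop("observations: guild must be one of ",
         paste(GUILDS, collapse = "/"), call. = FALSE)
  if (any(!is.finite(obs$year) | obs$year != round(obs$year)))
    stop("observations: year must be an integer", call. = FALSE)
  obs$year <- as.integer(obs$year)

  ## species attributes must be single-valued across the whole table
  for (attr in c("body_length_mm", "taxon_group", "guild")) {
    n_per_sp <- tapply(obs[[attr]], obs$species_id,
                       function(x) length(unique(x)))
    if (any(n_per_sp > 1))
      stop("observations: species with inconsistent ", attr, ": ",
           paste(utils::head(names(n_per_sp)[n_per_sp > 1], 5),
                 collapse = ", "), call. = FALSE)
  }

  if (!is.null(allometry)) {
    missing_tg <- setdiff(unique(obs$taxon_group), allometry$taxon_group)
    if (length(missing_tg))
      stop("observations: taxon group(s) absent from allometry: ",
           paste(missing_tg, collapse = ", "), call. = FALSE)
  }

  key <- do.call(paste, c(obs[c("plot_id", "year", "season", "replicate",
                                "species_id")], sep = "\r"))
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    warning("observations: ", n_dup,
            " duplicate (sampling, species) row(s) summed", call. = FALSE)
    counts <- rowsum(obs$count, key, reorder = FALSE)
    first <- !duplicated(key)
    obs <- obs[first, , drop = FALSE]
    obs$count <- as.integer(counts[match(key[first], rownames(counts)), 1])
  }
  rownames(obs) <- NULL
  obs
}

#' Read a plot covariate table
#'
#' Two schemas are recognized from the header: `plot_id,psr` (experiment
#' mode; sown plant species richness, constant per plot) or
#' `plot_id,year,lui` (real-world mode; yearly land-use intensity).
#'
#' @param path Path to a covariate CSV.
#' @return A data frame with attribute `covariate_mode` set to
#'   `"experiment"` or `"real_world"`.
#' @export
read_covariates <- function(path) {
  check_file(path, "covariates")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(plot_id = "character"))
  validate_covariates(tab)
}

#' @rdname read_covariates
#' @param tab A covariate data frame.
#' @export
validate_covariates <- function(tab) {
  if (all(c("plot_id", "psr") %in% names(tab))) {
    if (anyDuplicated(tab$plot_id))
      stop("covariates: PSR must be constant per plot (one row per plot)",
           call. = FALSE)
    if (any(tab$psr <= 0 | tab$psr != round(tab$psr)))
      stop("covariates: psr must be a positive integer", call. = FALSE)
    tab <- tab[c("plot_id", "psr")]
    attr(tab, "covariate_mode") <- "experiment"
  } else if (all(c("plot_id", "year", "lui") %in% names(tab))) {
    if (any(tab$lui < 0))
      stop("covariates: lui must be >= 0", call. = FALSE)
    if (anyDuplicated(paste(tab$plot_id, tab$year)))
      stop("covariates: one LUI value per plot and year", call. = FALSE)
    tab <- tab[c("plot_id", "year", "lui")]
    attr(tab, "covariate_mode") <- "real_world"
  } else {
    stop("covariates: expected columns plot_id,psr or plot_id,year,lui",
         call. = FALSE)
  }
  tab
}

#' Write a pipeline table as CSV with deterministic column order
#'
#' @param tab A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

check_file <- function(path, what) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    stop(what, ": file not found: ", path, call. = FALSE)
  invisible(path)
}

check_columns <- function(tab, cols, what) {
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

sample_key <- function(plot_id, year, replicate) {
  paste(plot_id, year, replicate, sep = "\r")
}
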