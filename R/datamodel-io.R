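# ---- core containers -------------------------------------------------------
#
# All site x species information travels as base matrices with mandatory
# dimnames: rows are sites, columns are species, in one canonical order fixed
# at read/generation time.  Occurrence matrices are integer 0/1, suitability
# matrices are numeric in [0,1], membership matrices are logical.  The method
# that produced a suitability or membership matrix is carried in the
# "method_tag" attribute.

#' Validate and canonicalize an occurrence matrix
#'
#' An occurrence matrix is a binary (0/1) site-by-species incidence matrix
#' with unique site identifiers as row names and unique species identifiers
#' as column names.
#'
#' @param x matrix-like object, sites in rows, species in columns.
#' @return integer matrix of class preserved as plain matrix, values in
#'   \{0, 1\}, with validated dimnames.
#' @export
as_occurrence <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("occurrence matrix needs site row names and species column names")
  if (anyDuplicated(rownames(x)))
    stop("duplicate site identifiers: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate species identifiers: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  storage.mode(x) <- "double"
  bad <- which(!(x %in% c(0, 1)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop(sprintf("non-binary incidence value %s at site '%s', species '%s'",
                 format(x[bad[1]]), rownames(x)[i], colnames(x)[j]))
  }
  storage.mode(x) <- "integer"
  x
}

#' Construct a site grid
#'
#' A site grid holds projected planar coordinates (km) of grid-cell centers.
#'
#' @param site_id character vector of unique site identifiers.
#' @param x,y numeric easting/northing of cell centers, km.
#' @param cell_size cell edge length in km (attribute only; coordinates may
#'   be arbitrary distinct points in the general case).
#' @return data.frame with columns site_id, x, y and attribute "cell_size".
#' @export
site_grid <- function(site_id, x, y, cell_size = NA_real_) {
  site_id <- as.character(site_id)
  if (anyDuplicated(site_id)) stop("duplicate site identifiers in grid")
  if (length(x) != length(site_id) || length(y) != length(site_id))
    stop("site_id, x, y must have equal length")
  g <- data.frame(site_id = site_id, x = as.numeric(x), y = as.numeric(y),
                  stringsAsFactors = FALSE)
  attr(g, "cell_size") <- cell_size
  class(g) <- c("site_grid", "data.frame")
  g
}

#' Validate an environment table
#'
#' @param x data.frame with a site_id column followed by numeric
#'   environmental variables; at most one column may be a factor/character
#'   (categorical cover class).
#' @return validated data.frame with site_id as character.
#' @export
as_env_table <- function(x) {
  x <- as.data.frame(x)
  if (!"site_id" %in% names(x)) stop("environment table needs a site_id column")
  x$site_id <- as.character(x$site_id)
  if (anyDuplicated(x$site_id)) stop("duplicate site identifiers in environment table")
  vars <- setdiff(names(x), "site_id")
  if (!length(vars)) stop("environment table has no variables")
  for (v in vars) {
    if (is.character(x[[v]])) x[[v]] <- factor(x[[v]])
    if (anyNA(x[[v]])) stop("missing values in environment variable '", v, "'")
  }
  n_cat <- sum(vapply(x[vars], is.factor, logical(1)))
  if (n_cat > 1) stop("at most one categorical environment variable is supported")
  x[c("site_id", vars)]
}

# internal: check two site-indexed objects share the same site ordering
check_aligned <- function(sites_a, sites_b, what = "inputs") {
  if (length(sites_a) != length(sites_b) || !all(sites_a == sites_b))
    stop(what, " are not aligned on the same ordered site set")
  invisible(TRUE)
}

#' Pipeline configuration
#'
#' Collects every tunable constant of the estimation pipeline.  Defaults are
#' the atlas-scale conventions: species kept only when occupying at least 20
#' cells, co-occurrence inclusion at the 5\% quantile of occupied-cell
#' suitabilities, an 80/20 calibration/evaluation split repeated 5 times,
#' a 500-km dispersal radius and a >50\% dispersion-field criterion.
#'
#' @param min_occ minimum number of occupied cells per species (inclusive).
#' @param sco_quantile per-species quantile of occupied-cell Beals values
#'   used as the dark-diversity inclusion threshold.
#' @param radius_km dispersal filter radius (km).
#' @param dispersion_fraction strict lower bound on the shared-species
#'   fraction defining the dispersion field.
#' @param sdm_split calibration fraction of the data split.
#' @param sdm_repeats number of random calibration/evaluation splits.
#' @param threshold_grid_size candidate-threshold grid size; NULL scans the
#'   sorted unique predicted values (plus 0 and 1).
#' @param include_focal_site logical; include the focal site in the
#'   co-occurrence counts (literal reading of the Beals formula) or use the
#'   leave-one-out variant.
#' @param overlap_universe hypergeometric universe N per site:
#'   "all_absent" counts every species absent from the site (the literal
#'   definition, default); "filtered" restricts the universe to absent
#'   species passing the spatial eligibility filters (the candidate pool
#'   both methods choose from, but statistically weak when dark sizes
#'   approach the universe size).
#' @param alpha significance level for the overlap-test summary.
#' @param seed integer seed recorded in all output metadata.
#' @return list of class "pipeline_config".
#' @export
pipeline_config <- function(min_occ = 20L,
                            sco_quantile = 0.05,
                            radius_km = 500,
                            dispersion_fraction = 0.5,
                            sdm_split = 0.8,
                            sdm_repeats = 5L,
                            threshold_grid_size = NULL,
                            include_focal_site = TRUE,
                            overlap_universe = c("all_absent", "filtered"),
                            alpha = 0.05,
                            seed = 1L) {
  stopifnot(min_occ >= 1, radius_km >= 0, sdm_repeats >= 1)
  for (f in c(sco_quantile, dispersion_fraction, sdm_split))
    if (!is.finite(f) || f <= 0 || f >= 1)
      stop("fractions must lie strictly in (0, 1)")
  cfg <- list(min_occ = as.integer(min_occ), sco_quantile = sco_quantile,
              radius_km = radius_km, dispersion_fraction = dispersion_fraction,
              sdm_split = sdm_split, sdm_repeats = as.integer(sdm_repeats),
              threshold_grid_size = threshold_grid_size,
              include_focal_site = isTRUE(include_focal_site),
              overlap_universe = match.arg(overlap_universe),
              alpha = alpha, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

# internal: "# key=value" metadata header lines for an output file
config_header <- function(config) {
  if (is.null(config)) return(character(0))
  flat <- config[!vapply(config, is.null, logical(1))]
  sprintf("# %s=%s", names(flat),
          vapply(flat, function(v) paste(format(v), collapse = ","), character(1)))
}

write_csv_with_header <- function(df, path, config = NULL) {
  lines <- config_header(config)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
}

# ---- readers / writers -----------------------------------------------------

#' Read a site-by-species occurrence CSV
#'
#' Expects a comma-separated UTF-8 file whose first column is site_id and
#' whose remaining columns are species with 0/1 incidence.  Lines starting
#' with "#" are metadata and skipped.
#'
#' @param path file path.
#' @return validated occurrence matrix (see [as_occurrence()]).
#' @export
read_occurrence <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!nrow(df) || ncol(df) < 2) stop("empty or malformed occurrence file: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_occurrence(m)
}

#' Write an occurrence matrix as CSV
#' @param occ occurrence matrix.
#' @param path file path.
#' @param config optional [pipeline_config()] echoed as "#" header lines.
#' @export
write_occurrence <- function(occ, path, config = NULL) {
  occ <- as_occurrence(occ)
  df <- data.frame(site_id = rownames(occ), occ, check.names = FALSE)
  write_csv_with_header(df, path, config)
  invisible(path)
}

#' Read a site grid CSV (site_id, x, y)
#' @param path file path.
#' @param cell_size optional cell size (km) recorded as an attribute.
#' @return a [site_grid()].
#' @export
read_grid <- function(path, cell_size = NA_real_) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("site_id", "x", "y") %in% names(df)))
    stop("grid file must have columns site_id, x, y")
  site_grid(df$site_id, df$x, df$y, cell_size)
}

#' Write a site grid CSV
#' @inheritParams write_occurrence
#' @param grid a [site_grid()].
#' @export
write_grid <- function(grid, path, config = NULL) {
  write_csv_with_header(as.data.frame(grid), path, config)
  invisible(path)
}

#' Read an environment CSV (site_id + variables)
#' @param path file path.
#' @return validated environment table.
#' @export
read_env <- function(path) {
  as_env_table(utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' Write an environment table as CSV
#' @inheritParams write_occurrence
#' @param env environment table.
#' @export
write_env <- function(env, path, config = NULL) {
  write_csv_with_header(as_env_table(env), path, config)
  invisible(path)
}

#' Write a membership matrix in long format
#'
#' Long CSV with columns site_id, species_id, method, member and (when a
#' suitability matrix is supplied) prob.
#'
#' @param membership logical site-by-species matrix with a "method_tag"
#'   attribute.
#' @param path file path.
#' @param prob optional aligned numeric suitability matrix.
#' @param config optional config echoed as header.
#' @export
write_membership <- function(membership, path, prob = NULL, config = NULL) {
  tag <- attr(membership, "method_tag")
  if (is.null(tag)) tag <- "unknown"
  df <- data.frame(
    site_id = rep(rownames(membership), times = ncol(membership)),
    species_id = rep(colnames(membership), each = nrow(membership)),
    method = tag,
    member = as.integer(as.vector(membership)))
  if (!is.null(prob)) df$prob <- as.vector(prob)
  write_csv_with_header(df, path, config)
  invisible(path)
}

#' Read a long-format membership CSV back into a matrix
#' @param path file path.
#' @return logical site-by-species matrix with "method_tag" attribute.
#' @export
read_membership <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  sites <- unique(df$site_id)
  species <- unique(df$species_id)
  m <- matrix(FALSE, length(sites), length(species),
              dimnames = list(sites, species))
  m[cbind(match(df$site_id, sites), match(df$species_id, species))] <-
    df$member > 0
  attr(m, "method_tag") <- df$method[1]
  m
}

# ---- minimum-occurrence filter --------------------------------------------

#' Drop species occupying fewer than min_occ cells
#'
#' The filter runs once, before both estimators; "at least" min_occ cells is
#' inclusive, so a species occupying exactly min_occ cells is retained.
#' Sites are kept even if the filter empties them.
#'
#' @param occ occurrence matrix.
#' @param min_occ minimum number of occupied cells (inclusive), >= 1.
#' @param verbose log removed species via [message()].
#' @return occurrence matrix containing the retained species; removed
#'   species ids are attached as attribute "removed_species".
#' @export
filter_min_occurrence <- function(occ, min_occ, verbose = FALSE) {
  occ <- as_occurrence(occ)
  if (min_occ < 1) stop("min_occ must be >= 1")
  n_k <- colSums(occ)
  keep <- n_k >= min_occ
  if (!any(keep)) stop("min-occurrence filter removed every species; nothing to analyze")
  removed <- colnames(occ)[!keep]
  if (verbose && length(removed))
    message("min-occurrence filter removed ", length(removed), " species: ",
            paste(removed, collapse = ", "))
  out <- occ[, keep, drop = FALSE]
  attr(out, "removed_species") <- removed
  out
}

# ---- summary I/O -----------------------------------------------------------

#' Write the per-site dark-diversity summary CSV
#'
#' Columns: site_id, observed_richness, dark_<method>..., then
#' completeness_<method>... Missing completeness (zero dark size or zero
#' richness) is written as an empty field.
#'
#' @param summary data.frame produced by [summarize_dark()].
#' @param path file path.
#' @param config optional config echoed as header.
#' @export
write_summary <- function(summary, path, config = NULL) {
  write_csv_with_header(summary, path, config)
  invisible(path)
}

#' Read a dark-diversity summary CSV
#' @param path file path.
#' @return data.frame; empty completeness fields become NA.
#' @export
read_summary <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df$site_id <- as.character(df$site_id)
  df
}
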