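# Dispersal and biogeographic eligibility filters applied to membership
# matrices: geographic radius filter and dispersion-field filter.  Filters
# only ever remove members.

#' Geographic radius eligibility
#'
#' A species is eligible at a site when it occurs in at least one cell whose
#' center lies within Euclidean distance <= radius_km of the site's center
#' (boundary inclusive; the focal cell counts, though a dark candidate is
#' absent there by construction).
#'
#' @param occ occurrence matrix.
#' @param grid aligned [site_grid()]; distances are planar, km.
#' @param radius_km radius, >= 0.
#' @return logical site-by-species eligibility matrix.
#' @export
radius_eligibility <- function(occ, grid, radius_km) {
  occ <- as_occurrence(occ)
  check_aligned(rownames(occ), grid$site_id, "occurrence and grid")
  if (radius_km < 0) stop("radius_km must be >= 0")
  within <- if (is.infinite(radius_km)) {
    matrix(1, nrow(occ), nrow(occ))
  } else {
    d <- as.matrix(stats::dist(cbind(grid$x, grid$y)))
    (d <= radius_km) * 1
  }
  elig <- (within %*% occ) > 0
  dimnames(elig) <- dimnames(occ)
  elig
}

#' Dispersion field of a focal site
#'
#' The set of sites sharing strictly more than \code{fraction} of the focal
#' site's species, plus the focal site itself.  A focal site with empty
#' composition yields only itself (the criterion is vacuous at zero
#' richness).
#'
#' @param occ occurrence matrix.
#' @param focal_site site identifier (row name of \code{occ}).
#' @param fraction strict lower bound on the shared fraction, in (0, 1).
#' @return character vector of site identifiers.
#' @export
dispersion_field <- function(occ, focal_site, fraction = 0.5) {
  occ <- as_occurrence(occ)
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  i <- match(focal_site, rownames(occ))
  if (is.na(i)) stop("unknown focal site: ", focal_site)
  s_focal <- sum(occ[i, ])
  if (s_focal == 0) return(rownames(occ)[i])
  shared <- as.vector(occ %*% occ[i, ])   # |composition(s) ∩ composition(focal)|
  region <- shared / s_focal > fraction
  region[i] <- TRUE
  rownames(occ)[region]
}

# internal: for every (site, species), does the species occur in at least
# one cell of the site's dispersion field?  Vectorized over sites.
dispersion_eligibility <- function(occ, fraction = 0.5) {
  occ <- as_occurrence(occ)
  I <- matrix(as.numeric(occ), nrow(occ), ncol(occ))
  s_i <- rowSums(I)
  shared <- tcrossprod(I)                     # shared[i, s]
  region <- sweep(shared, 1, pmax(s_i, 1), "/") > fraction
  region[s_i == 0, ] <- FALSE
  diag(region) <- TRUE                        # focal site always in its field
  elig <- (region %*% I) > 0
  dimnames(elig) <- dimnames(occ)
  elig
}

#' Apply dispersal and biogeographic filters to a membership matrix
#'
#' Pure conjunction: a member survives only if it is radius-eligible and
#' occurs in at least one site of the focal site's dispersion field.
#'
#' @param membership logical membership matrix.
#' @param occ aligned occurrence matrix (the filtered analysis matrix).
#' @param grid aligned [site_grid()].
#' @param config a [pipeline_config()] (uses radius_km,
#'   dispersion_fraction).
#' @return filtered membership matrix; per-filter removal counts are
#'   attached as attribute "removed_counts".
#' @export
apply_filters <- function(membership, occ, grid, config = pipeline_config()) {
  occ <- as_occurrence(occ)
  check_aligned(rownames(membership), rownames(occ), "membership and occurrence")
  check_aligned(colnames(membership), colnames(occ), "membership and occurrence species")
  r_elig <- radius_eligibility(occ, grid, config$radius_km)
  d_elig <- dispersion_eligibility(occ, config$dispersion_fraction)
  out <- membership & r_elig & d_elig
  attr(out, "method_tag") <- attr(membership, "method_tag")
  attr(out, "removed_counts") <- c(
    radius = sum(membership & !r_elig),
    dispersion_field = sum(membership & r_elig & !d_elig))
  out
}

# internal: the spatially eligible candidate universe (absent + both
# filters), used as the hypergeometric N in the "filtered" mode.
eligible_universe <- function(occ, grid, config) {
  (occ == 0L) &
    radius_eligibility(occ, grid, config$radius_km) &
    dispersion_eligibility(occ, config$dispersion_fraction)
}
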