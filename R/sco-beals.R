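# Species co-occurrence (SCO) estimator: Beals occurrence probabilities,
# per-species quantile thresholds, and dark-diversity membership.

#' Beals occurrence probabilities
#'
#' For every site i and species j computes
#' \deqn{P_{ij} = \frac{1}{S_i} \sum_{k \ne j} \frac{N_{jk} I_{ik}}{N_k}}
#' where \eqn{S_i} is the richness of site i excluding species j,
#' \eqn{N_{jk}} the number of joint occurrences of species j and k over all
#' sites, \eqn{I_{ik}} the incidence of k at i, and \eqn{N_k} the number of
#' occurrences of k.  P is defined for every (site, species) pair, present
#' or absent.
#'
#' With \code{include_focal_site = FALSE} the focal site's own contribution
#' is removed from all counts (the leave-one-out variant found elsewhere in
#' the literature); the default is the literal formula, in which counts run
#' over all sites including the focal one.
#'
#' Sites where \eqn{S_i = 0} for a focal species (empty or single-species
#' sites) carry no co-occurrence information; P is set to 0 there and the
#' sites are reported in the "flagged_sites" attribute.
#'
#' @param occ occurrence matrix, already min-occurrence filtered; every
#'   species must occupy at least one site.
#' @param include_focal_site logical, see above.
#' @return numeric site-by-species matrix in [0, 1] with attributes
#'   "method_tag" = "SCO" and "flagged_sites".
#' @export
beals_probabilities <- function(occ, include_focal_site = TRUE) {
  occ <- as_occurrence(occ)
  I <- matrix(as.numeric(occ), nrow(occ), ncol(occ), dimnames = dimnames(occ))
  n_k <- colSums(I)
  if (any(n_k < 1)) stop("species with zero occurrences: ",
                         paste(colnames(I)[n_k < 1], collapse = ", "))
  M <- crossprod(I)                      # N_jk joint occurrences, N_k on diagonal
  if (include_focal_site) {
    W <- sweep(M, 2, n_k, "/")           # W[j, k] = N_jk / N_k
    num <- I %*% t(W) - I                # subtract the k = j term (M_jj / N_j = 1)
    s_excl <- rowSums(I) - I             # S_i excluding the focal species
  } else {
    # leave-one-out: remove site i from N_k and N_jk before evaluating at i.
    n_site <- nrow(I); n_sp <- ncol(I)
    num <- matrix(0, n_site, n_sp, dimnames = dimnames(I))
    for (i in seq_len(n_site)) {
      pres <- I[i, ]
      Mk <- M - tcrossprod(pres)         # joint counts without site i
      nk <- n_k - pres
      ratio <- ifelse(rep(nk, each = n_sp) > 0, Mk / rep(nk, each = n_sp), 0)
      dim(ratio) <- dim(Mk)
      num[i, ] <- as.vector(ratio %*% pres) - pres * diag(ratio)
    }
    s_excl <- rowSums(I) - I
  }
  P <- ifelse(s_excl > 0, num / pmax(s_excl, 1), 0)
  P <- pmin(pmax(P, 0), 1)               # clamp float fuzz at the boundaries
  dimnames(P) <- dimnames(occ)
  attr(P, "method_tag") <- "SCO"
  attr(P, "flagged_sites") <- rownames(occ)[rowSums(occ) <= 1]
  P
}

#' Per-species dark-diversity inclusion thresholds
#'
#' The threshold of species j is the empirical q-quantile (linear
#' interpolation between order statistics, position h = (n - 1) q + 1) of
#' its suitability values in the cells where the species is present.
#'
#' @param P suitability matrix from [beals_probabilities()].
#' @param occ aligned occurrence matrix.
#' @param q quantile in (0, 1); 0 gives the minimum occupied-cell value.
#' @return named numeric vector of thresholds, one per species.
#' @export
species_thresholds <- function(P, occ, q = 0.05) {
  check_aligned(colnames(P), colnames(occ), "suitability and occurrence species")
  check_aligned(rownames(P), rownames(occ), "suitability and occurrence sites")
  if (q < 0 || q >= 1) stop("quantile must lie in [0, 1)")
  n_k <- colSums(occ)
  if (any(n_k < 1)) stop("species with zero occupied sites: ",
                         paste(colnames(occ)[n_k < 1], collapse = ", "))
  vapply(seq_len(ncol(occ)), function(j) {
    stats::quantile(P[occ[, j] == 1L, j], probs = q, names = FALSE, type = 7)
  }, numeric(1)) |> stats::setNames(colnames(occ))
}

#' Species co-occurrence dark-diversity membership
#'
#' A species is a dark-diversity member at a site when it is absent there
#' and its occurrence probability strictly exceeds its per-species
#' threshold.
#'
#' @param P suitability matrix.
#' @param occ aligned occurrence matrix.
#' @param thresholds named vector from [species_thresholds()].
#' @return logical membership matrix with "method_tag" = "SCO".
#' @export
sco_membership <- function(P, occ, thresholds) {
  check_aligned(colnames(P), colnames(occ), "suitability and occurrence species")
  check_aligned(colnames(occ), names(thresholds), "occurrence and thresholds")
  member <- (occ == 0L) & sweep(P, 2, thresholds, ">")
  dimnames(member) <- dimnames(occ)
  attr(member, "method_tag") <- "SCO"
  member
}

#' One-call SCO estimator
#'
#' Convenience wrapper: Beals probabilities, thresholds, membership.
#'
#' @param occ min-occurrence-filtered occurrence matrix.
#' @param q threshold quantile.
#' @param include_focal_site see [beals_probabilities()].
#' @return list with suitability (P), thresholds, membership.
#' @export
sco_dark <- function(occ, q = 0.05, include_focal_site = TRUE) {
  P <- beals_probabilities(occ, include_focal_site = include_focal_site)
  th <- species_thresholds(P, occ, q = q)
  list(suitability = P, thresholds = th,
       membership = sco_membership(P, occ, th))
}
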