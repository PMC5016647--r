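# Consensus / composite combination of per-method memberships, dark sizes,
# and completeness of site diversity.

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)) ||
      !identical(rownames(a), rownames(b)) ||
      !identical(colnames(a), colnames(b)))
    stop("membership matrices have mismatched site or species labels")
}

#' Consensus dark diversity (intersection of two methods)
#'
#' Species assigned to dark diversity by both methods: cellwise AND.
#'
#' @param memA,memB aligned logical membership matrices.
#' @return membership matrix with method_tag "consensus".
#' @export
dark_consensus <- function(memA, memB) {
  check_same_shape(memA, memB)
  out <- memA & memB
  attr(out, "method_tag") <- "consensus"
  out
}

#' Composite dark diversity (union of two methods)
#'
#' Species assigned by at least one method: cellwise OR.
#'
#' @param memA,memB aligned logical membership matrices.
#' @return membership matrix with method_tag "composite".
#' @export
dark_composite <- function(memA, memB) {
  check_same_shape(memA, memB)
  out <- memA | memB
  attr(out, "method_tag") <- "composite"
  out
}

#' Per-site dark sizes and completeness of site diversity
#'
#' Completeness is ln(observed richness / dark diversity); it is undefined
#' (NA, written as an empty CSV field) when the dark size or the observed
#' richness is zero, and such sites are excluded from downstream
#' correlations rather than given a pseudo-count.
#'
#' @param occ occurrence matrix.
#' @param memberships named list of aligned membership matrices (names are
#'   used as method tags in the column names).
#' @return data.frame: site_id, observed_richness, dark_<tag>...,
#'   completeness_<tag>...
#' @export
summarize_dark <- function(occ, memberships) {
  occ <- as_occurrence(occ)
  if (is.null(names(memberships)) || any(names(memberships) == ""))
    stop("memberships must be a named list")
  s <- rowSums(occ)
  out <- data.frame(site_id = rownames(occ), observed_richness = as.integer(s),
                    stringsAsFactors = FALSE)
  for (tag in names(memberships)) {
    m <- memberships[[tag]]
    check_aligned(rownames(m), rownames(occ), paste0("membership '", tag, "'"))
    out[[paste0("dark_", tag)]] <- as.integer(rowSums(m))
  }
  for (tag in names(memberships)) {
    d <- out[[paste0("dark_", tag)]]
    out[[paste0("completeness_", tag)]] <-
      ifelse(d > 0 & s > 0, log(s / pmax(d, 1)), NA_real_)
  }
  out
}
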