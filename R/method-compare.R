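# Statistics comparing two dark-diversity estimates: overlap coefficient,
# exact hypergeometric overlap tests with site summaries, and type II
# (major-axis) regression of ln dark sizes against the 1:1 line.

#' Overlap coefficient of two species sets
#'
#' |A intersect B| / min(|A|, |B|): compositional agreement robust to the
#' size difference between the two estimates.  Missing (NA) when either set
#' is empty.
#'
#' @param setA,setB character vectors (species identifiers).
#' @return fraction in [0, 1], or NA.
#' @export
overlap_coefficient <- function(setA, setB) {
  setA <- unique(setA); setB <- unique(setB)
  m <- min(length(setA), length(setB))
  if (m == 0) return(NA_real_)
  length(intersect(setA, setB)) / m
}

#' Exact hypergeometric overlap probability
#'
#' Upper-tail probability P(X >= overlap) where X is the overlap obtained
#' by drawing x1 species at random without replacement from a universe of N
#' species of which x2 belong to the second method's dark diversity:
#' X ~ Hypergeometric(N, x2, x1).
#'
#' @param N universe size (species absent from the site and eligible).
#' @param x1 dark size by the first method.
#' @param x2 dark size by the second method.
#' @param overlap observed overlap count.
#' @return probability in (0, 1].
#' @export
hypergeom_overlap_p <- function(N, x1, x2, overlap) {
  for (v in c(N, x1, x2, overlap))
    if (length(v) != 1 || !is.finite(v) || v < 0 || v != round(v))
      stop("arguments must be single non-negative integers")
  if (x1 > N) stop("bound violated: x1 <= N required")
  if (x2 > N) stop("bound violated: x2 <= N required")
  if (overlap > min(x1, x2)) stop("bound violated: overlap <= min(x1, x2) required")
  if (overlap < max(0, x1 + x2 - N))
    stop("bound violated: overlap >= max(0, x1 + x2 - N) required")
  stats::phyper(overlap - 1, m = x2, n = N - x2, k = x1, lower.tail = FALSE)
}

#' Summaries of per-site overlap tests
#'
#' @param p_values numeric vector of per-site hypergeometric p-values (NAs
#'   dropped).
#' @param alpha significance level for the exceedance fraction.
#' @return list: mean_p, median_p, fraction_p_above_alpha, n.
#' @export
overlap_summary <- function(p_values, alpha = 0.05) {
  p <- p_values[!is.na(p_values)]
  if (!length(p)) stop("no defined p-values to summarize")
  list(mean_p = mean(p), median_p = stats::median(p),
       fraction_p_above_alpha = mean(p > alpha), n = length(p))
}

#' Type II (major-axis) regression
#'
#' Fits the major axis of the bivariate scatter: slope
#' \deqn{b = \frac{s_{yy} - s_{xx} + \sqrt{(s_{yy} - s_{xx})^2 + 4 s_{xy}^2}}{2 s_{xy}}}
#' with the line through the means.  The slope confidence interval uses the
#' classical one-degree-of-freedom F-based interval
#' (Jolicoeur's method): with eigenvalues l1 >= l2 of the sample covariance
#' matrix, H = F(ci_level; 1, n-2) / ((l1/l2 + l2/l1 - 2)(n - 2)),
#' A = sqrt(H / (1 - H)), and slope limits tan(atan(b) +- atan(A)).
#' R-squared is the squared Pearson correlation.
#'
#' @param x,y numeric vectors, n >= 3, neither constant.
#' @param ci_level confidence level, default 0.95.
#' @return list (Type2Fit): slope, intercept, slope_ci_low, slope_ci_high,
#'   r2, n, includes_one.
#' @export
major_axis_fit <- function(x, y, ci_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("major-axis regression needs at least 3 points")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0) stop("x and y must not be constant")
  if (sxy == 0) stop("zero covariance: major-axis slope undefined (axis-aligned scatter)")
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  intercept <- mean(y) - slope * mean(x)
  ev <- eigen(matrix(c(sxx, sxy, sxy, syy), 2), symmetric = TRUE)$values
  H <- stats::qf(ci_level, 1, n - 2) / ((ev[1] / ev[2] + ev[2] / ev[1] - 2) * (n - 2))
  if (!is.finite(H) || H >= 1) {
    lo <- -Inf; hi <- Inf          # CI spans all directions
  } else {
    delta <- atan(sqrt(H / (1 - H)))
    theta <- atan(slope)
    lo <- theta - delta; hi <- theta + delta
    # tan() wraps beyond +-pi/2: a CI crossing the vertical is unbounded
    lo <- if (lo <= -pi / 2) -Inf else tan(lo)
    hi <- if (hi >= pi / 2) Inf else tan(hi)
  }
  r2 <- stats::cor(x, y)^2
  list(slope = slope, intercept = intercept,
       slope_ci_low = lo, slope_ci_high = hi,
       r2 = r2, n = n, includes_one = (lo <= 1 && 1 <= hi))
}

#' Full method comparison
#'
#' Per-site overlap tests between two membership matrices plus a type II
#' regression of ln dark sizes.  The hypergeometric universe N is, per
#' site, the number of species absent from the site (mode "all_absent",
#' the default); mode "filtered" further restricts the universe to species
#' passing the spatial eligibility filters (the candidate pool both
#' methods choose from, but a weak null when dark sizes approach the
#' universe size).  Sites where a
#' method has zero dark size are excluded from the regression (count
#' reported); sites with an empty universe or an empty smaller set yield NA
#' overlap statistics.
#'
#' @param memA,memB aligned membership matrices (typically already
#'   spatially filtered).
#' @param occ aligned occurrence matrix.
#' @param grid [site_grid()], required for the "filtered" universe.
#' @param config a [pipeline_config()] (uses overlap_universe, radius_km,
#'   dispersion_fraction, alpha).
#' @return list of class "comparison_report": \code{sites} (data.frame of
#'   per-site OverlapTest records), \code{overlap} (p-value and coefficient
#'   summaries), \code{regression} (Type2Fit or NULL), \code{n_excluded_regression}.
#' @export
compare_methods <- function(memA, memB, occ, grid = NULL,
                            config = pipeline_config()) {
  occ <- as_occurrence(occ)
  check_same_shape(memA, memB)
  check_aligned(rownames(memA), rownames(occ), "membership and occurrence")
  universe <- if (config$overlap_universe == "filtered") {
    if (is.null(grid)) stop("grid required for the filtered overlap universe")
    eligible_universe(occ, grid, config)
  } else {
    occ == 0L
  }
  # memberships outside the universe would break the hypergeometric bounds
  inA <- memA & universe
  inB <- memB & universe
  n_site <- nrow(occ)
  sites <- data.frame(
    site_id = rownames(occ),
    N = as.integer(rowSums(universe)),
    x1 = as.integer(rowSums(inA)),
    x2 = as.integer(rowSums(inB)),
    overlap = as.integer(rowSums(inA & inB)),
    stringsAsFactors = FALSE)
  sites$overlap_coefficient <- ifelse(
    pmin(sites$x1, sites$x2) > 0, sites$overlap / pmin(sites$x1, sites$x2),
    NA_real_)
  sites$p_value <- vapply(seq_len(n_site), function(i) {
    if (sites$N[i] == 0) return(NA_real_)
    hypergeom_overlap_p(sites$N[i], sites$x1[i], sites$x2[i], sites$overlap[i])
  }, numeric(1))
  usable <- sites$x1 > 0 & sites$x2 > 0
  reg <- NULL
  if (sum(usable) >= 3) {
    reg <- tryCatch(
      major_axis_fit(log(sites$x1[usable]), log(sites$x2[usable])),
      error = function(e) { warning(conditionMessage(e)); NULL })
  } else {
    warning("fewer than 3 sites with both dark sizes positive; regression omitted")
  }
  out <- list(
    sites = sites,
    overlap = c(overlap_summary(sites$p_value, config$alpha),
                list(mean_overlap_coefficient =
                       mean(sites$overlap_coefficient, na.rm = TRUE),
                     median_overlap_coefficient =
                       stats::median(sites$overlap_coefficient, na.rm = TRUE))),
    regression = reg,
    n_excluded_regression = sum(!usable))
  class(out) <- "comparison_report"
  out
}

#' Write a comparison report as JSON
#'
#' @param report a "comparison_report" from [compare_methods()].
#' @param path file path.
#' @param config optional config embedded under "config".
#' @export
write_comparison <- function(report, path, config = NULL) {
  payload <- list(
    overlap = report$overlap,
    regression = report$regression,
    n_excluded_regression = report$n_excluded_regression)
  if (!is.null(config)) payload$config <- unclass(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}
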