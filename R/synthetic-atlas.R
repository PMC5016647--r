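# Synthetic atlas generator: gridded landscape, smooth environmental
# gradients, virtual species with Gaussian niches, dispersal-limited ranges,
# and Bernoulli-sampled occurrences with a known ground-truth dark diversity.

#' Generate a regular square-cell grid
#'
#' Cell centers lie at ((i + 0.5) * cell_size, (j + 0.5) * cell_size) for
#' i in 0..nx-1, j in 0..ny-1; site ids are "s<col>_<row>".
#'
#' @param nx,ny number of columns/rows, >= 1.
#' @param cell_size cell edge length, km.
#' @return a [site_grid()].
#' @export
generate_grid <- function(nx, ny, cell_size) {
  if (nx < 1 || ny < 1) stop("grid dimensions must be >= 1")
  if (cell_size <= 0) stop("cell_size must be positive")
  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  site_grid(sprintf("s%02d_%02d", ij$i + 1L, ij$j + 1L),
            (ij$i + 0.5) * cell_size,
            (ij$j + 0.5) * cell_size,
            cell_size)
}

#' Generate smooth environmental variables on a grid
#'
#' Each variable is a linear south-to-north gradient of the stated amplitude
#' plus spatially autocorrelated Gaussian noise with exponential
#' distance-decaying covariance \eqn{noise\_scale^2 exp(-d / autocorr\_range)}.
#' Deterministic given the seed.
#'
#' @param grid a [site_grid()].
#' @param n_vars number of variables, >= 1.
#' @param gradient_amplitude units spanned by the gradient end to end.
#' @param noise_scale marginal standard deviation of the spatial noise.
#' @param autocorr_range e-folding range of the noise covariance, km.
#' @param seed integer seed.
#' @return environment table with variables env1..env<n_vars>.
#' @export
generate_environment <- function(grid, n_vars = 4L, gradient_amplitude = 10,
                                 noise_scale = 3, autocorr_range = 200,
                                 seed = 1L) {
  if (n_vars < 1) stop("n_vars must be >= 1")
  if (noise_scale < 0 || autocorr_range < 0) stop("scales must be non-negative")
  n <- nrow(grid)
  yspan <- diff(range(grid$y))
  gradient <- if (yspan > 0) (grid$y - min(grid$y)) / yspan * gradient_amplitude
              else rep(0, n)
  vars <- matrix(rep(gradient, n_vars), n, n_vars)
  if (noise_scale > 0) {
    d <- as.matrix(stats::dist(cbind(grid$x, grid$y)))
    sigma <- noise_scale^2 * exp(-d / max(autocorr_range, 1e-9))
    cl <- chol(sigma + diag(1e-8, n))
    set.seed(seed)
    vars <- vars + t(cl) %*% matrix(stats::rnorm(n * n_vars), n, n_vars)
  }
  colnames(vars) <- paste0("env", seq_len(n_vars))
  as_env_table(data.frame(site_id = grid$site_id, vars))
}

#' Generate a pool of virtual species with Gaussian niches
#'
#' Niche optima are drawn uniformly within each variable's observed span;
#' niche breadths are drawn (per variable) uniformly within
#' \code{niche_breadth_range}, expressed in standard deviations of that
#' variable; peak occurrence probabilities are uniform within
#' \code{max_prob_range}.  Exactly \code{round(range_limited_fraction *
#' n_species)} species are dispersal-limited: they receive a random occupied
#' site as range center and a finite range radius, which guarantees
#' suitable-but-absent cells outside the range.
#'
#' @param n_species number of species.
#' @param env environment table (continuous variables only are used for
#'   niche placement).
#' @param grid a [site_grid()] supplying coordinates for range centers.
#' @param niche_breadth_range interval (in per-variable standard deviations).
#' @param max_prob_range interval in (0, 1].
#' @param range_limited_fraction fraction of species given a finite range.
#' @param range_radius_range interval of range radii, km, for limited species.
#' @param seed integer seed.
#' @return data.frame of class "niche_pool": one row per species with
#'   species_id, max_prob, range_x, range_y, range_radius (Inf when
#'   unlimited), and matrix columns optimum / breadth (species x variable).
#' @export
generate_species_pool <- function(n_species, env, grid,
                                  niche_breadth_range = c(1, 3),
                                  max_prob_range = c(0.3, 0.9),
                                  range_limited_fraction = 0.4,
                                  range_radius_range = c(200, 500),
                                  seed = 1L) {
  stopifnot(n_species >= 1,
            niche_breadth_range[1] > 0, diff(niche_breadth_range) >= 0,
            max_prob_range[1] > 0, max_prob_range[2] <= 1,
            range_limited_fraction >= 0, range_limited_fraction <= 1)
  vars <- names(env)[vapply(env, is.numeric, logical(1))]
  vars <- setdiff(vars, "site_id")
  set.seed(seed)
  opt <- sapply(vars, function(v) stats::runif(n_species, min(env[[v]]), max(env[[v]])))
  bre <- sapply(vars, function(v)
    stats::runif(n_species, niche_breadth_range[1], niche_breadth_range[2]) *
      max(stats::sd(env[[v]]), 1e-9))
  opt <- matrix(opt, n_species, length(vars), dimnames = list(NULL, vars))
  bre <- matrix(bre, n_species, length(vars), dimnames = list(NULL, vars))
  max_prob <- stats::runif(n_species, max_prob_range[1], max_prob_range[2])
  n_limited <- round(range_limited_fraction * n_species)
  limited <- rep(FALSE, n_species)
  if (n_limited > 0) limited[sample.int(n_species, n_limited)] <- TRUE
  center_idx <- sample.int(nrow(grid), n_species, replace = TRUE)
  radius <- ifelse(limited,
                   stats::runif(n_species, range_radius_range[1], range_radius_range[2]),
                   Inf)
  pool <- data.frame(species_id = sprintf("sp%03d", seq_len(n_species)),
                     max_prob = max_prob,
                     range_x = grid$x[center_idx],
                     range_y = grid$y[center_idx],
                     range_radius = radius,
                     stringsAsFactors = FALSE)
  pool$optimum <- opt
  pool$breadth <- bre
  class(pool) <- c("niche_pool", "data.frame")
  pool
}

# internal: true occurrence probability of every species at every site.
# Gaussian (unimodal) response: max_prob * exp(-sum_v (env_v - opt_v)^2 /
# (2 breadth_v^2)); zero outside a limited species' range.
true_suitability_matrix <- function(grid, env, pool) {
  vars <- colnames(pool$optimum)
  E <- as.matrix(env[vars])
  n_site <- nrow(E); n_sp <- nrow(pool)
  suit <- matrix(0, n_site, n_sp, dimnames = list(grid$site_id, pool$species_id))
  for (s in seq_len(n_sp)) {
    z <- sweep(E, 2, pool$optimum[s, ], "-")
    z <- sweep(z, 2, pool$breadth[s, ], "/")
    suit[, s] <- pool$max_prob[s] * exp(-rowSums(z^2) / 2)
  }
  suit
}

in_range_matrix <- function(grid, pool) {
  d2 <- outer(grid$x, pool$range_x, "-")^2 + outer(grid$y, pool$range_y, "-")^2
  sweep(sqrt(d2), 2, pool$range_radius, "<=")
}

#' Sample occurrences and ground-truth dark diversity
#'
#' Occurrence of species j at site i is an independent Bernoulli draw with
#' probability equal to the true suitability inside the species' dispersal
#' range and 0 outside.  A (site, species) cell is true dark when the
#' species is absent there and its suitability is at least
#' \code{truth_cutoff * max_prob}.  Two truth variants are emitted: with the
#' dispersal range ignored (\code{true_dark}) and with true-dark status
#' restricted to cells inside the range (\code{true_dark_in_range}); which
#' one applies depends on whether the dispersal filter is under evaluation.
#'
#' @param grid a [site_grid()].
#' @param env environment table aligned with the grid.
#' @param pool niche pool from [generate_species_pool()].
#' @param truth_cutoff suitability cutoff as a fraction of each species'
#'   peak probability.
#' @param seed integer seed.
#' @return list with elements \code{occ} (occurrence matrix) and
#'   \code{truth}, itself a list of matrices \code{true_suitability},
#'   \code{true_dark}, \code{true_dark_in_range}, plus \code{truth_cutoff}
#'   and \code{seed}.
#' @export
sample_occurrences <- function(grid, env, pool, truth_cutoff = 0.5, seed = 1L) {
  check_aligned(grid$site_id, env$site_id, "grid and environment")
  suit <- true_suitability_matrix(grid, env, pool)
  inr <- in_range_matrix(grid, pool)
  p <- suit * inr
  set.seed(seed)
  occ <- matrix(as.integer(stats::runif(length(p)) < p), nrow(p), ncol(p),
                dimnames = dimnames(suit))
  suitable <- sweep(suit, 2, truth_cutoff * pool$max_prob, ">=")
  true_dark <- (occ == 0L) & suitable
  list(occ = as_occurrence(occ),
       truth = list(true_suitability = suit,
                    true_dark = true_dark,
                    true_dark_in_range = true_dark & inr,
                    truth_cutoff = truth_cutoff,
                    seed = as.integer(seed)))
}

#' Default synthetic-atlas scenario
#'
#' The reference test bed: a 20 x 20 grid of 50-km cells, 4 environmental
#' variables, 80 virtual species (40\% dispersal-limited), minimum
#' occurrence of 20 cells applied after sampling.
#'
#' @param nx,ny,cell_size grid dimensions.
#' @param n_vars number of environmental variables.
#' @param n_species number of virtual species.
#' @param min_occ minimum-occurrence filter applied to the sampled matrix.
#' @param seed integer seed driving every random stage.
#' @param ... passed on to [generate_species_pool()].
#' @return list with grid, env, pool, occ (filtered), occ_raw, truth.
#' @export
synthetic_scenario <- function(nx = 20L, ny = 20L, cell_size = 50,
                               n_vars = 4L, n_species = 80L, min_occ = 20L,
                               seed = 1L, ...) {
  grid <- generate_grid(nx, ny, cell_size)
  env <- generate_environment(grid, n_vars = n_vars, seed = seed)
  pool <- generate_species_pool(n_species, env, grid, seed = seed + 1L, ...)
  samp <- sample_occurrences(grid, env, pool, seed = seed + 2L)
  occ <- filter_min_occurrence(samp$occ, min_occ)
  list(grid = grid, env = env, pool = pool,
       occ = occ, occ_raw = samp$occ, truth = samp$truth)
}

#' Write the ground-truth table as long CSV
#'
#' Columns: site_id, species_id, true_suitability, true_dark,
#' true_dark_in_range.
#'
#' @param truth truth list from [sample_occurrences()].
#' @param path file path.
#' @param config optional config echoed as header.
#' @export
write_truth <- function(truth, path, config = NULL) {
  ts <- truth$true_suitability
  df <- data.frame(
    site_id = rep(rownames(ts), times = ncol(ts)),
    species_id = rep(colnames(ts), each = nrow(ts)),
    true_suitability = as.vector(ts),
    true_dark = as.integer(as.vector(truth$true_dark)),
    true_dark_in_range = as.integer(as.vector(truth$true_dark_in_range)))
  write_csv_with_header(df, path, config)
  invisible(path)
}
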