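# Species distribution modelling (SDM) estimator: per-species binomial
# additive models, repeated 80/20 calibration/evaluation splits, TSS-optimal
# binarization, and dark-diversity membership.

# internal: model formula for one species over the environment table.
# Continuous variables get modest thin-plate smooths (k = 4) with shrinkage
# (select = TRUE at fit time); a categorical variable enters as levels.
sdm_formula <- function(env) {
  vars <- setdiff(names(env), "site_id")
  terms <- vapply(vars, function(v) {
    if (is.numeric(env[[v]])) sprintf("s(%s, k = 4)", v) else v
  }, character(1))
  stats::as.formula(paste("occ ~", paste(terms, collapse = " + ")))
}

#' Fit one species' distribution model
#'
#' Binomial additive model with logit link; smooth terms for continuous
#' variables with a modest smoothness budget (basis dimension 4 per
#' variable) and automatic shrinkage.  On failure or non-convergence the
#' fit falls back to logistic regression with linear + quadratic terms; the
#' fallback is recorded.
#'
#' @param env environment table (rows aligned with \code{occ_j}).
#' @param occ_j binary occurrence vector for the species.
#' @param seed integer; kept for interface symmetry (fitting is
#'   deterministic given the data).
#' @return list with \code{predict(newenv)} returning probabilities in
#'   [0, 1], and \code{fallback} flag.
#' @export
fit_species_model <- function(env, occ_j, seed = 1L) {
  if (length(occ_j) != nrow(env)) stop("occurrence vector and environment are not aligned")
  if (sum(occ_j) < 1 || sum(occ_j) >= length(occ_j))
    stop("species needs at least one presence and one absence")
  dat <- env[setdiff(names(env), "site_id")]
  dat$occ <- as.numeric(occ_j)
  fit <- tryCatch({
    m <- mgcv::gam(sdm_formula(env), family = stats::binomial("logit"),
                   data = dat, method = "REML", select = TRUE)
    if (!m$converged) stop("gam did not converge")
    m
  }, error = function(e) NULL)
  fallback <- is.null(fit)
  if (fallback) {
    vars <- setdiff(names(env), "site_id")
    terms <- vapply(vars, function(v) {
      if (is.numeric(env[[v]])) sprintf("%s + I(%s^2)", v, v) else v
    }, character(1))
    f <- stats::as.formula(paste("occ ~", paste(terms, collapse = " + ")))
    fit <- stats::glm(f, family = stats::binomial("logit"), data = dat)
  }
  list(
    predict = function(newenv) {
      nd <- newenv[setdiff(names(newenv), "site_id")]
      p <- as.numeric(stats::predict(fit, newdata = nd, type = "response"))
      pmin(pmax(p, 0), 1)
    },
    fallback = fallback)
}

#' Random calibration/evaluation site splits
#'
#' Each repeat partitions the sites at the stated proportion (calibration
#' size = \code{round(fraction * n)}); partitions are random, differ across
#' repeats, and are deterministic given the seed.
#'
#' @param n_sites number of sites.
#' @param calibration_fraction fraction in (0, 1).
#' @param repeats number of splits, >= 1.
#' @param seed integer seed.
#' @return list of length \code{repeats}; each element a list with integer
#'   index vectors \code{calibration} and \code{evaluation}.
#' @export
split_sites <- function(n_sites, calibration_fraction = 0.8, repeats = 5L,
                        seed = 1L) {
  if (calibration_fraction <= 0 || calibration_fraction >= 1)
    stop("calibration_fraction must lie in (0, 1)")
  if (repeats < 1) stop("repeats must be >= 1")
  n_cal <- round(calibration_fraction * n_sites)
  if (n_cal < 1 || n_cal >= n_sites)
    stop("split leaves an empty calibration or evaluation set")
  set.seed(seed)
  lapply(seq_len(repeats), function(r) {
    cal <- sort(sample.int(n_sites, n_cal))
    list(calibration = cal, evaluation = setdiff(seq_len(n_sites), cal))
  })
}

#' TSS-optimal binarization threshold
#'
#' Scans candidate thresholds and returns the one maximizing the true skill
#' statistic TSS = sensitivity + specificity - 1, where a prediction is
#' positive when \code{pred >= threshold}.  Candidates are the sorted unique
#' predicted values plus 0 and 1 (default), or an even grid of
#' \code{grid_size} points in [0, 1].  Ties are broken toward the smallest
#' threshold.
#'
#' @param pred numeric predicted probabilities.
#' @param obs binary observations containing both classes.
#' @param grid_size NULL for the data-driven candidate set, or a count.
#' @return list (one ThresholdFit): threshold, tss, sensitivity,
#'   specificity, n_eval.
#' @export
tss_best_threshold <- function(pred, obs, grid_size = NULL) {
  obs <- as.integer(obs)
  if (length(pred) != length(obs)) stop("pred and obs lengths differ")
  n_pos <- sum(obs == 1L); n_neg <- sum(obs == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("observations contain a single class; TSS threshold undefined")
  cand <- if (is.null(grid_size)) sort(unique(c(0, pred, 1)))
          else seq(0, 1, length.out = grid_size)
  best <- list(threshold = cand[1], tss = -Inf, sensitivity = NA_real_,
               specificity = NA_real_, n_eval = length(obs))
  for (t in cand) {
    pos <- pred >= t
    sens <- sum(pos & obs == 1L) / n_pos
    spec <- sum(!pos & obs == 0L) / n_neg
    tss <- sens + spec - 1
    if (tss > best$tss) {             # strict improvement: ties keep smallest t
      best <- list(threshold = t, tss = tss, sensitivity = sens,
                   specificity = spec, n_eval = length(obs))
    }
  }
  best
}

#' SDM dark-diversity membership
#'
#' Per species: repeated random calibration/evaluation splits; a model
#' fitted on each calibration set predicts its evaluation set, where the
#' TSS-optimal threshold is found; per-repeat thresholds are aggregated by
#' their arithmetic mean; a final model fitted on all sites supplies the
#' predictions that are binarized.  A species is a member at a site when it
#' is absent there and its final predicted probability is at or above its
#' aggregated threshold.
#'
#' Species whose model and fallback both fail, or whose evaluation sets are
#' single-class in every repeat, are excluded from membership and listed in
#' the "excluded_species" attribute.
#'
#' @param env environment table aligned with \code{occ}.
#' @param occ min-occurrence-filtered occurrence matrix.
#' @param config a [pipeline_config()] (uses sdm_split, sdm_repeats,
#'   threshold_grid_size, seed).
#' @return list with \code{membership} (logical matrix, method_tag "SDM"),
#'   \code{suitability} (final predicted probabilities, method_tag "SDM"),
#'   and \code{thresholds} (data.frame: species_id, threshold, tss,
#'   sensitivity, specificity, n_eval, fallback_used).
#' @export
sdm_membership <- function(env, occ, config = pipeline_config()) {
  env <- as_env_table(env)
  occ <- as_occurrence(occ)
  check_aligned(env$site_id, rownames(occ), "environment and occurrence")
  n_site <- nrow(occ)
  splits <- split_sites(n_site, config$sdm_split, config$sdm_repeats,
                        seed = config$seed)
  species <- colnames(occ)
  member <- matrix(FALSE, n_site, ncol(occ), dimnames = dimnames(occ))
  suit <- matrix(NA_real_, n_site, ncol(occ), dimnames = dimnames(occ))
  fits <- vector("list", length(species))
  excluded <- character(0)
  for (j in seq_along(species)) {
    occ_j <- occ[, j]
    rep_fits <- list()
    fallback_any <- FALSE
    for (sp in splits) {
      obs_eval <- occ_j[sp$evaluation]
      if (length(unique(obs_eval)) < 2L) next   # single-class evaluation set
      m <- tryCatch(
        fit_species_model(env[sp$calibration, , drop = FALSE],
                          occ_j[sp$calibration], seed = config$seed),
        error = function(e) NULL)
      if (is.null(m)) next
      fallback_any <- fallback_any || m$fallback
      pred_eval <- m$predict(env[sp$evaluation, , drop = FALSE])
      rep_fits[[length(rep_fits) + 1L]] <-
        tss_best_threshold(pred_eval, obs_eval, config$threshold_grid_size)
    }
    final <- tryCatch(fit_species_model(env, occ_j, seed = config$seed),
                      error = function(e) NULL)
    if (!length(rep_fits) || is.null(final)) {
      excluded <- c(excluded, species[j])
      next
    }
    fallback_any <- fallback_any || final$fallback
    thr <- mean(vapply(rep_fits, `[[`, numeric(1), "threshold"))
    p <- final$predict(env)
    suit[, j] <- p
    member[, j] <- (occ_j == 0L) & (p >= thr)
    fits[[j]] <- data.frame(
      species_id = species[j], threshold = thr,
      tss = mean(vapply(rep_fits, `[[`, numeric(1), "tss")),
      sensitivity = mean(vapply(rep_fits, `[[`, numeric(1), "sensitivity")),
      specificity = mean(vapply(rep_fits, `[[`, numeric(1), "specificity")),
      n_eval = sum(vapply(rep_fits, `[[`, numeric(1), "n_eval")),
      fallback_used = fallback_any)
  }
  thresholds <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  attr(member, "method_tag") <- "SDM"
  attr(member, "excluded_species") <- excluded
  attr(suit, "method_tag") <- "SDM"
  list(membership = member, suitability = suit, thresholds = thresholds)
}
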