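# End-to-end pipeline and a small command-line front end.

#' Run the full dark-diversity pipeline
#'
#' Simulates (or accepts) an atlas dataset, estimates dark diversity by the
#' species co-occurrence and distribution-modelling methods, applies the
#' spatial filters, combines the methods into consensus and composite
#' memberships, summarizes sizes and completeness, and compares the two
#' methods.  When \code{out_dir} is given, every table is written as CSV
#' (with a "#" metadata header echoing the configuration, including the
#' seed) and the comparison as JSON; outputs are deterministic given the
#' configuration, so re-running a seed reproduces them byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL to skip writing.
#' @param occ,grid,env optional pre-built inputs; when \code{occ} is NULL a
#'   synthetic scenario is generated from \code{config$seed} with
#'   [synthetic_scenario()] defaults and \code{config$min_occ}.
#' @param verbose log progress via [message()].
#' @return (invisibly) list with occ, grid, env, truth (when simulated),
#'   sco, sdm (estimator outputs), membership (named list: sco, sdm,
#'   consensus, composite — all spatially filtered), summary, comparison.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         occ = NULL, grid = NULL, env = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  truth <- NULL
  if (is.null(occ)) {
    say("simulating synthetic atlas (seed ", config$seed, ")")
    sc <- synthetic_scenario(min_occ = config$min_occ, seed = config$seed)
    occ <- sc$occ; grid <- sc$grid; env <- sc$env; truth <- sc$truth
  } else {
    occ <- filter_min_occurrence(as_occurrence(occ), config$min_occ)
    if (is.null(grid) || is.null(env)) stop("grid and env are required with a supplied occurrence matrix")
    check_aligned(grid$site_id, rownames(occ), "grid and occurrence")
    check_aligned(env$site_id, rownames(occ), "environment and occurrence")
  }
  say("SCO estimator on ", nrow(occ), " sites x ", ncol(occ), " species")
  sco <- sco_dark(occ, q = config$sco_quantile,
                  include_focal_site = config$include_focal_site)
  say("SDM estimator (", config$sdm_repeats, " splits)")
  sdm <- sdm_membership(env, occ, config)
  say("spatial filters: radius ", config$radius_km, " km, dispersion fraction ",
      config$dispersion_fraction)
  mem_sco <- apply_filters(sco$membership, occ, grid, config)
  mem_sdm <- apply_filters(sdm$membership, occ, grid, config)
  membership <- list(sco = mem_sco, sdm = mem_sdm,
                     consensus = dark_consensus(mem_sco, mem_sdm),
                     composite = dark_composite(mem_sco, mem_sdm))
  summary <- summarize_dark(occ, membership)
  comparison <- compare_methods(mem_sco, mem_sdm, occ, grid, config)
  out <- list(occ = occ, grid = grid, env = env, truth = truth,
              sco = sco, sdm = sdm, membership = membership,
              summary = summary, comparison = comparison)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_occurrence(occ, p("occurrence.csv"), config)
    write_grid(grid, p("grid.csv"), config)
    write_env(env, p("environment.csv"), config)
    if (!is.null(truth)) write_truth(truth, p("truth.csv"), config)
    write_membership(mem_sco, p("membership_sco.csv"), sco$suitability, config)
    write_membership(mem_sdm, p("membership_sdm.csv"), sdm$suitability, config)
    write_membership(membership$consensus, p("membership_consensus.csv"), config = config)
    write_membership(membership$composite, p("membership_composite.csv"), config = config)
    if (!is.null(sdm$thresholds))
      write_csv_with_header(sdm$thresholds, p("sdm_thresholds.csv"), config)
    write_summary(summary, p("summary.csv"), config)
    write_comparison(comparison, p("comparison.json"), config)
    say("outputs written to ", out_dir)
  }
  invisible(out)
}

# ---- command line ----------------------------------------------------------

cli_parse <- function(args) {
  opts <- list(); pos <- character(0); i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  list(opts = opts, pos = pos)
}

cli_config <- function(opts) {
  cfg <- pipeline_config()
  num <- function(k, d) if (!is.null(opts[[k]])) as.numeric(opts[[k]]) else d
  pipeline_config(
    min_occ = num("min-occ", cfg$min_occ),
    sco_quantile = num("sco-quantile", cfg$sco_quantile),
    radius_km = num("radius-km", cfg$radius_km),
    dispersion_fraction = num("dispersion-fraction", cfg$dispersion_fraction),
    sdm_split = num("sdm-split", cfg$sdm_split),
    sdm_repeats = num("sdm-repeats", cfg$sdm_repeats),
    alpha = num("alpha", cfg$alpha),
    seed = num("seed", cfg$seed))
}

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write a synthetic atlas), \code{estimate
#' --method \{sco,sdm,both\}}, \code{filter}, \code{combine},
#' \code{compare}, and \code{pipeline} (everything in one run).  Shared
#' flags: \code{--out-dir}, \code{--seed}, \code{--verbose}, plus the
#' [pipeline_config()] constants as \code{--min-occ}, \code{--sco-quantile},
#' \code{--radius-km}, \code{--dispersion-fraction}, \code{--sdm-split},
#' \code{--sdm-repeats}, \code{--alpha}.  File-based subcommands read
#' \code{--occurrence}, \code{--grid}, \code{--env}, \code{--membership-a},
#' \code{--membership-b}.
#'
#' @param args character vector, default [commandArgs()] trailing args.
#' @return invisibly, the result of the subcommand.
#' @export
darkatlas_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: darkatlas <simulate|estimate|filter|combine|compare|pipeline> [--flags]\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  parsed <- cli_parse(args[-1])
  opts <- parsed$opts
  cfg <- cli_config(opts)
  out_dir <- if (!is.null(opts[["out-dir"]])) opts[["out-dir"]] else "."
  verbose <- isTRUE(opts[["verbose"]])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(k) {
    if (is.null(opts[[k]])) stop("missing required flag --", k)
    opts[[k]]
  }
  res <- switch(cmd,
    simulate = {
      sc <- synthetic_scenario(min_occ = cfg$min_occ, seed = cfg$seed)
      write_occurrence(sc$occ, file.path(out_dir, "occurrence.csv"), cfg)
      write_grid(sc$grid, file.path(out_dir, "grid.csv"), cfg)
      write_env(sc$env, file.path(out_dir, "environment.csv"), cfg)
      write_truth(sc$truth, file.path(out_dir, "truth.csv"), cfg)
      sc
    },
    estimate = {
      method <- if (!is.null(opts[["method"]])) opts[["method"]] else "both"
      occ <- filter_min_occurrence(read_occurrence(need("occurrence")), cfg$min_occ)
      res <- list()
      if (method %in% c("sco", "both")) {
        sco <- sco_dark(occ, q = cfg$sco_quantile,
                        include_focal_site = cfg$include_focal_site)
        write_membership(sco$membership, file.path(out_dir, "membership_sco.csv"),
                         sco$suitability, cfg)
        res$sco <- sco
      }
      if (method %in% c("sdm", "both")) {
        env <- read_env(need("env"))
        sdm <- sdm_membership(env, occ, cfg)
        write_membership(sdm$membership, file.path(out_dir, "membership_sdm.csv"),
                         sdm$suitability, cfg)
        write_csv_with_header(sdm$thresholds,
                              file.path(out_dir, "sdm_thresholds.csv"), cfg)
        res$sdm <- sdm
      }
      res
    },
    filter = {
      occ <- read_occurrence(need("occurrence"))
      grid <- read_grid(need("grid"))
      mem <- read_membership(need("membership-a"))
      filt <- apply_filters(mem, occ, grid, cfg)
      write_membership(filt, file.path(out_dir, "membership_filtered.csv"),
                       config = cfg)
      filt
    },
    combine = {
      occ <- read_occurrence(need("occurrence"))
      a <- read_membership(need("membership-a"))
      b <- read_membership(need("membership-b"))
      mem <- list(a = a, b = b,
                  consensus = dark_consensus(a, b),
                  composite = dark_composite(a, b))
      names(mem)[1:2] <- c(attr(a, "method_tag"), attr(b, "method_tag"))
      write_membership(mem$consensus, file.path(out_dir, "membership_consensus.csv"),
                       config = cfg)
      write_membership(mem$composite, file.path(out_dir, "membership_composite.csv"),
                       config = cfg)
      smry <- summarize_dark(occ, mem)
      write_summary(smry, file.path(out_dir, "summary.csv"), cfg)
      smry
    },
    compare = {
      occ <- read_occurrence(need("occurrence"))
      grid <- if (!is.null(opts[["grid"]])) read_grid(opts[["grid"]]) else NULL
      a <- read_membership(need("membership-a"))
      b <- read_membership(need("membership-b"))
      rep <- compare_methods(a, b, occ, grid, cfg)
      write_comparison(rep, file.path(out_dir, "comparison.json"), cfg)
      write_csv_with_header(rep$sites, file.path(out_dir, "overlap_tests.csv"), cfg)
      rep
    },
    pipeline = run_pipeline(cfg, out_dir, verbose = verbose),
    stop("unknown subcommand: ", cmd))
  invisible(res)
}
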