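test_that("site splits have the stated proportions and are seeded", {
  sp <- split_sites(10, 0.8, repeats = 3, seed = 1)
  for (s in sp) {
    expect_length(s$calibration, 8)
    expect_length(s$evaluation, 2)
    expect_length(intersect(s$calibration, s$evaluation), 0)
    expect_setequal(c(s$calibration, s$evaluation), 1:10)
  }
  expect_false(identical(sp[[1]], sp[[2]]))            # repeats differ
  expect_identical(sp, split_sites(10, 0.8, repeats = 3, seed = 1))
  expect_false(identical(sp, split_sites(10, 0.8, repeats = 3, seed = 2)))
  expect_error(split_sites(10, 0.999, repeats = 1, seed = 1), "empty")
  expect_error(split_sites(10, 1.2, repeats = 1, seed = 1), "\\(0, 1\\)")
})

test_that("TSS threshold matches the exhaustive-scan oracle on random instances", {
  # worked case: best TSS 0.5 at the smallest optimal candidate
  fit <- tss_best_threshold(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))
  expect_equal(fit$tss, 0.5)
  expect_equal(fit$threshold, 0.4)
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 0.5)
  expect_equal(fit$sensitivity + fit$specificity - 1, fit$tss)

  # perfect separation and uninformative predictions
  expect_equal(tss_best_threshold(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))$tss, 1)
  expect_equal(tss_best_threshold(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$tss, 0)
  expect_error(tss_best_threshold(runif(5), rep(1, 5)), "single class")

  set.seed(7)
  for (case in 1:100) {
    pred <- round(runif(20), 3)
    obs <- c(1, 0, rbinom(18, 1, 0.5))   # both classes guaranteed
    fit <- tss_best_threshold(pred, obs)
    expect_identical(fit$tss, tss_oracle(pred, obs))
    expect_true(fit$tss >= -1 && fit$tss <= 1)
  }
})

test_that("TSS of a random predictor on balanced data is near zero", {
  set.seed(42)
  pred <- runif(2000)
  obs <- rbinom(2000, 1, 0.5)
  expect_lt(abs(tss_best_threshold(pred, obs)$tss), 0.15)
})

test_that("species models: strong signal recovered, constant env falls back to prevalence", {
  grid <- generate_grid(20, 20, 50)
  env <- generate_environment(grid, 2, seed = 11)
  # perfectly separated occurrence along env1
  occ_j <- as.integer(env$env1 > stats::median(env$env1))
  sp <- split_sites(400, 0.8, repeats = 1, seed = 3)[[1]]
  # perfect separation pushes the logit fit to its iteration limit: expected
  m <- suppressWarnings(fit_species_model(env[sp$calibration, ], occ_j[sp$calibration]))
  fit <- tss_best_threshold(m$predict(env[sp$evaluation, ]), occ_j[sp$evaluation])
  expect_gt(fit$tss, 0.9)

  # determinism
  m2 <- suppressWarnings(fit_species_model(env[sp$calibration, ], occ_j[sp$calibration]))
  expect_equal(m$predict(env), m2$predict(env), tolerance = 0)

  # constant environment: fallback engaged, prediction ~ prevalence
  envc <- env; envc$env1 <- 1; envc$env2 <- 2
  set.seed(9)
  occ_r <- rbinom(400, 1, 0.3)
  mc <- fit_species_model(envc, occ_r)
  expect_true(mc$fallback)
  expect_equal(mean(mc$predict(envc)), mean(occ_r), tolerance = 1e-6)
  expect_equal(unname(diff(range(mc$predict(envc)))), 0)

  expect_error(fit_species_model(env, rep(1L, 400)), "presence and one absence")
})

test_that("sdm_membership: members absent, deterministic, thresholds consistent", {
  sc <- synthetic_scenario(nx = 12, ny = 12, n_species = 30, min_occ = 12, seed = 3)
  cfg <- pipeline_config(min_occ = 12, sdm_repeats = 2, seed = 3)
  res <- sdm_membership(sc$env, sc$occ, cfg)
  expect_true(all(!(res$membership & sc$occ == 1L)))
  expect_true(all(res$suitability >= 0 & res$suitability <= 1, na.rm = TRUE))
  expect_true(all(res$thresholds$threshold >= 0 & res$thresholds$threshold <= 1))
  expect_true(all(res$thresholds$tss >= -1 & res$thresholds$tss <= 1))

  res2 <- sdm_membership(sc$env, sc$occ, cfg)
  expect_identical(res$membership, res2$membership)
  expect_equal(res$suitability, res2$suitability, tolerance = 0)

  # a species predicted entirely below threshold contributes no members
  below <- res$thresholds$species_id[
    apply(res$suitability[, res$thresholds$species_id, drop = FALSE], 2, max) <
      res$thresholds$threshold]
  if (length(below))
    expect_equal(sum(res$membership[, below]), 0)
})
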