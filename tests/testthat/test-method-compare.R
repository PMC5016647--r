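test_that("overlap coefficient: forced arithmetic and invariances", {
  expect_equal(overlap_coefficient(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(overlap_coefficient(c("a", "b"), c("c", "d")), 0)
  expect_equal(overlap_coefficient(letters[1:4], letters[c(1:3, 5:7)]), 0.75)
  expect_true(is.na(overlap_coefficient(character(0), c("a"))))
  set.seed(5)
  for (i in 1:20) {
    A <- sample(letters, sample(1:10, 1))
    B <- sample(letters, sample(1:10, 1))
    v <- overlap_coefficient(A, B)
    expect_identical(v, overlap_coefficient(B, A))
    expect_true(v >= 0 && v <= 1)
  }
})

test_that("hypergeometric overlap p matches exhaustive enumeration", {
  expect_equal(hypergeom_overlap_p(5, 2, 3, 2), 0.3)   # 3 of the C(5,2)=10 draws
  expect_equal(hypergeom_overlap_p(10, 10, 4, 4), 1)   # degenerate full draw
  expect_equal(hypergeom_overlap_p(8, 3, 5, 0), 1)     # whole support

  for (N in c(4, 7, 10)) for (x1 in 0:N) for (x2 in 0:N) {
    lo <- max(0, x1 + x2 - N); hi <- min(x1, x2)
    for (ov in lo:hi)
      expect_equal(hypergeom_overlap_p(N, x1, x2, ov),
                   hyper_oracle(N, x1, x2, ov), tolerance = 1e-12)
    # tail monotone in the overlap
    ps <- vapply(lo:hi, function(ov) hypergeom_overlap_p(N, x1, x2, ov), numeric(1))
    expect_true(all(diff(ps) <= 1e-12))
  }
  expect_error(hypergeom_overlap_p(5, 6, 2, 1), "x1 <= N")
  expect_error(hypergeom_overlap_p(5, 2, 2, 3), "overlap <= min")
  expect_error(hypergeom_overlap_p(5, 4, 4, 1), "overlap >=")
})

test_that("overlap summaries aggregate as stated", {
  s <- overlap_summary(rep(0.01, 4), alpha = 0.05)
  expect_equal(c(s$mean_p, s$median_p, s$fraction_p_above_alpha), c(0.01, 0.01, 0))
  s2 <- overlap_summary(c(0.01, 0.5), alpha = 0.05)
  expect_equal(c(s2$mean_p, s2$median_p, s2$fraction_p_above_alpha),
               c(0.255, 0.255, 0.5))
  expect_error(overlap_summary(NA_real_), "no defined")
})

test_that("major-axis regression: exact line, swap, eigen oracle, CI coverage", {
  x <- 1:10
  f <- major_axis_fit(x, 2 * x)
  expect_equal(f$slope, 2)
  expect_equal(f$r2, 1)
  expect_equal(f$intercept, 0)

  set.seed(17)
  for (i in 1:10) {
    xs <- rnorm(60); ys <- 0.8 * xs + rnorm(60, sd = 0.7)
    fit <- major_axis_fit(xs, ys)
    expect_equal(fit$slope, ma_eigen_oracle(xs, ys), tolerance = 1e-9)
    swap <- major_axis_fit(ys, xs)
    expect_equal(swap$slope, 1 / fit$slope, tolerance = 1e-9)
    expect_true(fit$slope_ci_low <= fit$slope && fit$slope <= fit$slope_ci_high)
    # translation invariance and common-scale equivariance
    shift <- major_axis_fit(xs + 5, ys - 3)
    expect_equal(shift$slope, fit$slope, tolerance = 1e-9)
    scaled <- major_axis_fit(3 * xs, 3 * ys)
    expect_equal(scaled$slope, fit$slope, tolerance = 1e-9)
  }

  # isotropic bivariate normal with true axis slope 1: CI contains 1
  set.seed(23)
  z <- matrix(rnorm(400), 200, 2) %*% chol(matrix(c(1, 0.6, 0.6, 1), 2))
  fit1 <- major_axis_fit(z[, 1], z[, 2])
  expect_true(fit1$includes_one)

  expect_error(major_axis_fit(1:2, 2:3), "at least 3")
  expect_error(major_axis_fit(rep(1, 5), rnorm(5)), "constant")
  expect_error(major_axis_fit(c(1, 2, 1, 2), c(5, 5, 7, 7)), "covariance")
})

test_that("major-axis CI has approximately nominal Monte Carlo coverage", {
  set.seed(31)
  cover <- replicate(300, {
    z <- matrix(rnorm(120), 60, 2) %*% chol(matrix(c(1, 0.5, 0.5, 1), 2))
    major_axis_fit(z[, 1], z[, 2])$includes_one
  })
  expect_gt(mean(cover), 0.88)   # nominal 0.95; binomial noise at 300 reps
  expect_lt(mean(cover), 0.995)
})

test_that("compare_methods: identical inputs, null overlap, report structure", {
  occ <- random_occ(30, 15, p = 0.3, seed = 91)
  grid <- generate_grid(6, 5, 50)
  rownames(occ) <- grid$site_id
  set.seed(13)
  mem <- (occ == 0L) & matrix(runif(length(occ)) < 0.4, nrow(occ))
  dimnames(mem) <- dimnames(occ)
  cfg <- pipeline_config(min_occ = 1)

  rep_same <- compare_methods(mem, mem, occ, grid, cfg)
  oc <- rep_same$sites$overlap_coefficient
  expect_true(all(oc[!is.na(oc)] == 1))
  expect_equal(rep_same$regression$slope, 1, tolerance = 1e-9)
  expect_equal(rep_same$regression$r2, 1, tolerance = 1e-9)

  # independent random memberships of fixed per-site sizes: p not small
  set.seed(29)
  mk <- function() {
    m <- matrix(FALSE, nrow(occ), ncol(occ), dimnames = dimnames(occ))
    for (i in seq_len(nrow(occ))) {
      absent <- which(occ[i, ] == 0L)
      m[i, sample(absent, min(5, length(absent)))] <- TRUE
    }
    m
  }
  # constant ln sizes make the regression degenerate here, which warns and
  # omits it; the overlap statistics are the point of this fixture
  meds <- replicate(20, suppressWarnings({
    r <- compare_methods(mk(), mk(), occ, grid, cfg)
    stats::median(r$sites$p_value, na.rm = TRUE)
  }))
  expect_gt(mean(meds), 0.2)

  # per-site records respect the hypergeometric bounds
  r <- suppressWarnings(compare_methods(mk(), mk(), occ, grid, cfg))
  s <- r$sites
  expect_true(all(s$overlap <= pmin(s$x1, s$x2)))
  expect_true(all(s$overlap >= pmax(0, s$x1 + s$x2 - s$N)))
  expect_true(all(s$p_value > 0 & s$p_value <= 1, na.rm = TRUE))

  # JSON report round-trip
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison(r, path, cfg)
  js <- jsonlite::read_json(path)
  expect_equal(js$overlap$median_p, stats::median(s$p_value, na.rm = TRUE),
               tolerance = 1e-12)
  expect_equal(js$regression$slope, r$regression$slope, tolerance = 1e-12)
})

test_that("filtered-universe mode restricts N and keeps bounds valid", {
  occ <- random_occ(25, 12, p = 0.35, seed = 101)
  grid <- generate_grid(5, 5, 50)
  rownames(occ) <- grid$site_id
  set.seed(37)
  mem_a <- (occ == 0L) & matrix(runif(length(occ)) < 0.3, nrow(occ))
  mem_b <- (occ == 0L) & matrix(runif(length(occ)) < 0.3, nrow(occ))
  dimnames(mem_a) <- dimnames(mem_b) <- dimnames(occ)
  cfg_all <- pipeline_config(min_occ = 1, overlap_universe = "all_absent")
  cfg_fil <- pipeline_config(min_occ = 1, overlap_universe = "filtered",
                             radius_km = 100)
  r_all <- compare_methods(mem_a, mem_b, occ, grid, cfg_all)
  r_fil <- compare_methods(mem_a, mem_b, occ, grid, cfg_fil)
  expect_true(all(r_fil$sites$N <= r_all$sites$N))
  expect_equal(r_all$sites$N, unname(rowSums(occ == 0L)))
  s <- r_fil$sites
  expect_true(all(s$overlap <= pmin(s$x1, s$x2)))
  expect_true(all(s$x1 <= s$N & s$x2 <= s$N))
})
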