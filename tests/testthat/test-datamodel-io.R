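test_that("occurrence CSV round-trips and rejects bad input", {
  occ <- random_occ(3, 2, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrence(occ, path, pipeline_config())
  back <- read_occurrence(path)
  expect_identical(back, as_occurrence(occ))

  # non-binary cell named in the error
  bad <- occ
  storage.mode(bad) <- "double"
  bad[2, 1] <- 2
  writeLines(c("site_id,sp1,sp2",
               apply(cbind(rownames(bad), bad), 1, paste, collapse = ",")),
             path)
  expect_error(read_occurrence(path), "s2.*sp1")

  # empty file is a hard error
  writeLines("site_id", path)
  expect_error(read_occurrence(path), "empty|malformed")

  # duplicate labels rejected
  dup <- occ
  rownames(dup) <- c("s1", "s1", "s3")
  expect_error(as_occurrence(dup), "duplicate site")
})

test_that("grid, environment, membership and summary tables round-trip", {
  grid <- generate_grid(3, 2, 10)
  env <- generate_environment(grid, 2, seed = 5)
  gpath <- withr::local_tempfile(fileext = ".csv")
  epath <- withr::local_tempfile(fileext = ".csv")
  write_grid(grid, gpath)
  write_env(env, epath)
  g2 <- read_grid(gpath)
  expect_equal(g2$site_id, grid$site_id)
  expect_equal(g2$x, grid$x)
  expect_equal(g2$y, grid$y)
  e2 <- read_env(epath)
  expect_equal(e2$site_id, env$site_id)
  expect_equal(e2$env1, env$env1, tolerance = 1e-12)

  occ <- random_occ(6, 4, seed = 7)
  mem <- (occ == 0L) & matrix(rbinom(24, 1, 0.5) == 1, 6, 4)
  dimnames(mem) <- dimnames(occ)
  attr(mem, "method_tag") <- "SCO"
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_membership(mem, mpath, config = pipeline_config())
  m2 <- read_membership(mpath)
  expect_identical(unname(m2 == TRUE), unname(mem == TRUE))
  expect_identical(attr(m2, "method_tag"), "SCO")

  smry <- summarize_dark(occ, list(sco = mem))
  spath <- withr::local_tempfile(fileext = ".csv")
  write_summary(smry, spath, pipeline_config())
  s2 <- read_summary(spath)
  expect_identical(s2$observed_richness, smry$observed_richness)
  expect_identical(s2$dark_sco, smry$dark_sco)
  # metadata header records the seed
  expect_true(any(grepl("^# seed=1$", readLines(spath))))
})

test_that("completeness conventions in the summary file", {
  # site a: S = 10, D = 5 -> completeness ln 2; site b: D = 0 -> empty field
  occ <- matrix(0L, 2, 15, dimnames = list(c("a", "b"), paste0("sp", 1:15)))
  occ[1, 1:10] <- 1L; occ[2, 1:10] <- 1L
  mem <- matrix(FALSE, 2, 15, dimnames = dimnames(occ))
  mem[1, 11:15] <- TRUE
  smry <- summarize_dark(occ, list(sco = mem))
  expect_equal(smry$completeness_sco[1], log(2))
  expect_true(is.na(smry$completeness_sco[2]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary(smry, path)
  row_b <- grep("^b,", readLines(path), value = TRUE)
  expect_true(endsWith(row_b, ","))   # missing completeness as empty field
  expect_true(is.na(read_summary(path)$completeness_sco[2]))
})

test_that("minimum-occurrence filter is inclusive, logged and idempotent", {
  occ <- matrix(0L, 30, 3, dimnames = list(paste0("s", 1:30), c("a", "b", "c")))
  occ[1:25, 1] <- 1L; occ[1:19, 2] <- 1L; occ[1:20, 3] <- 1L
  out <- filter_min_occurrence(occ, 20)
  expect_identical(colnames(out), c("a", "c"))     # "at least" 20 keeps 20
  expect_identical(attr(out, "removed_species"), "b")

  expect_identical(colnames(filter_min_occurrence(occ, 1)), colnames(occ))
  expect_error(filter_min_occurrence(occ, 26), "every species")
  expect_error(filter_min_occurrence(occ, 0), ">= 1")

  # oracle: retained set equals a direct column-sum scan; idempotence
  m <- random_occ(50, 30, p = 0.35, seed = 99)
  f <- filter_min_occurrence(m, 15)
  expect_identical(colnames(f), colnames(m)[colSums(m) >= 15])
  expect_identical(as.vector(filter_min_occurrence(f, 15)), as.vector(f))
})
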