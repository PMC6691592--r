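test_that("write/read round trip preserves scores, missingness and order", {
  dat <- sim_mutualism_data(n = 40, seed = 3, missing_rate = 0.15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_wide_csv(dat, path)
  cmap <- setNames(colnames(dat$scores), colnames(dat$scores))
  back <- read_wide_csv(path, cmap)
  expect_identical(is.na(back$scores), is.na(dat$scores))
  expect_equal(back$scores, dat$scores, ignore_attr = TRUE)
})

test_that("missing tokens become NA and bad cells raise parse errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  header <- "v1,v2,m1,m2"
  writeLines(c(header, "1,2,3,4", "5,NA,7,8"), path)
  cmap <- c(v1 = "voc_t1", v2 = "voc_t2", m1 = "mat_t1", m2 = "mat_t2")
  dat <- read_wide_csv(path, cmap, wave_labels = c("T1", "T2"))
  expect_equal(sum(is.na(dat$scores)), 1L)
  expect_true(is.na(dat$scores[2, "voc_t2"]))
  rep <- attr(dat, "validation")
  expect_equal(rep$n_missing[rep$variable == "voc_t2"], 1L)

  writeLines(c(header, "1,2,oops,4"), path)
  expect_error(read_wide_csv(path, cmap, wave_labels = c("T1", "T2")),
               "parse error.*oops.*m1.*row 1")
})

test_that("degenerate files and unmapped columns are configuration errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("v1,v2,m1,m2", path)
  cmap <- c(v1 = "voc_t1", v2 = "voc_t2", m1 = "mat_t1", m2 = "mat_t2")
  expect_error(read_wide_csv(path, cmap, wave_labels = c("T1", "T2")),
               "empty file")
  writeLines(c("v1,v2,m1", "1,2,3"), path)
  expect_error(read_wide_csv(path, cmap, wave_labels = c("T1", "T2")),
               "configuration error")
  expect_error(read_wide_csv(tempfile(), cmap), "not found")
})

test_that("describe matches hand arithmetic and flags degenerate variables", {
  sc <- cbind(voc_t1 = c(1, 3), voc_t2 = c(5, 5),
              mat_t1 = c(2, NA), mat_t2 = c(NA, 7))
  dat <- suppressWarnings(
    longitudinal_data(sc, c("T1", "T2"), c("voc", "mat")))
  d <- describe(dat)
  expect_equal(d$mean[d$variable == "voc_t1"], 2)
  expect_equal(d$variance[d$variable == "voc_t1"], 2) # n-1 divisor
  expect_equal(d$variance[d$variable == "voc_t2"], 0) # constant column
  expect_true(is.na(d$variance[d$variable == "mat_t1"]))
  expect_match(d$flag[d$variable == "mat_t1"], "undefined")
})

test_that("sample covariance converges to the generating covariance", {
  cfg <- mutualism_generating_preset(coupling = 0.2, n = 10000)
  dat <- simulate_dataset(cfg, seed = 99)
  implied <- implied_moments(cfg$spec, cfg$true_values)
  sample_cov <- attr(describe(dat), "cov")
  expect_lt(max(abs(sample_cov - implied$sigma) / (abs(implied$sigma) + 1)),
            0.05)
})

test_that("all-missing persons are flagged, not silently dropped", {
  sc <- rbind(c(1, 2, 3, 4), rep(NA_real_, 4))
  colnames(sc) <- c("voc_t1", "voc_t2", "mat_t1", "mat_t2")
  expect_warning(longitudinal_data(sc, c("T1", "T2"), c("voc", "mat")),
                 "no observed scores")
})

test_that("yaml study configuration reads the column map", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("column_map:", "  Voc_W2: voc_t1", "  Voc_W3: voc_t2",
               "domains: [voc, mat]"), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$column_map[["Voc_W2"]], "voc_t1")
  expect_equal(cfg$domains, c("voc", "mat"))
})
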