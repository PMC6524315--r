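test_that("proteinuria coding follows the three strict thresholds", {
  expect_true(derive_proteinuria(25, NA, NA))
  expect_false(derive_proteinuria(10, 0.2, 15))
  expect_true(derive_proteinuria(NA, 0.31, NA))
  # strict comparisons: values exactly at the threshold are negative
  expect_false(derive_proteinuria(20, 0.3, 20))
  expect_error(derive_proteinuria(NA, NA, NA), "undeterminable")
  expect_true(is.na(derive_proteinuria(NA, NA, NA, na_undeterminable = TRUE)))
})

test_that("proteinuria is monotone in every component", {
  set.seed(11)
  for (i in 1:50) {
    comps <- list(runif(1, 0, 40), runif(1, 0, 0.6), runif(1, 0, 40))
    drop <- sample(0:2, 1)
    if (drop > 0) for (j in sample(3, drop)) comps[[j]] <- NA
    if (all(is.na(unlist(comps)))) comps[[1]] <- 5
    base <- derive_proteinuria(comps[[1]], comps[[2]], comps[[3]])
    j <- sample(which(!is.na(unlist(comps))), 1)
    comps[[j]] <- comps[[j]] + runif(1, 0, 50)
    raised <- derive_proteinuria(comps[[1]], comps[[2]], comps[[3]])
    if (base) expect_true(raised)
  }
})

test_that("CKD-EPI eGFR matches the hand-evaluated closed form", {
  # 141 * (0.7/0.7)^-0.329 * 1 * 0.993^50 * 1.018, evaluated by hand
  expect_equal(egfr_ckdepi(0.7, 50, "female"), 101.02509, tolerance = 1e-6)
  expect_gt(egfr_ckdepi(0.7, 50, "male"), egfr_ckdepi(0.7, 50, "female"))
  expect_lt(egfr_ckdepi(1.4, 50, "female"), egfr_ckdepi(0.7, 50, "female"))
  expect_lt(egfr_ckdepi(0.7, 70, "female"), egfr_ckdepi(0.7, 50, "female"))
  expect_error(egfr_ckdepi(-1, 50, "female"), "positive")
})

test_that("creatinine_from_egfr inverts the CKD-EPI equation", {
  for (scr in c(0.4, 0.7, 1.2, 3.5)) {
    for (sex in c("female", "male")) {
      g <- egfr_ckdepi(scr, 62, sex)
      expect_equal(ctpirp:::creatinine_from_egfr(g, 62, sex), scr,
                   tolerance = 1e-10)
    }
  }
})

test_that("CKD stages partition (0, Inf) with the published bands", {
  expect_equal(as.character(ckd_stage(95)), "1-2")
  expect_equal(as.character(ckd_stage(50)), "3a")
  expect_equal(as.character(ckd_stage(12)), "5")
  # no gaps or overlaps across the boundaries
  x <- c(14.999, 15, 29.999, 30, 44.999, 45, 59.999, 60, 200)
  expect_false(any(is.na(ckd_stage(x))))
  expect_equal(as.character(ckd_stage(c(15, 30, 45, 60))),
               c("4", "3b", "3a", "1-2"))
})

test_that("annual eGFR slope recovers exact and noisy trajectories", {
  dates <- as.Date("2010-01-01") + round(c(0, 0.5, 1, 1.5, 2) * 365.25)
  t_years <- as.numeric(dates - dates[1]) / 365.25
  # build creatinine so that recomputed eGFR is exactly linear at -3/yr
  target <- 60 - 3 * t_years
  cr <- ctpirp:::creatinine_from_egfr(target, 55 + t_years, "male")
  expect_equal(egfr_annual_slope(dates, cr, 55, "male"), -3, tolerance = 1e-9)

  flat <- ctpirp:::creatinine_from_egfr(rep(45, 5), 55 + t_years, "male")
  expect_equal(egfr_annual_slope(dates, flat, 55, "male"), 0,
               tolerance = 1e-9)

  set.seed(3)
  noisy_g <- 60 - 3 * t_years + rnorm(5)
  cr2 <- ctpirp:::creatinine_from_egfr(noisy_g, 55 + t_years, "male")
  expect_equal(egfr_annual_slope(dates, cr2, 55, "male"),
               oracle_ols_slope(t_years, noisy_g), tolerance = 1e-9)

  # invariance to shifting all dates by a constant number of days
  expect_equal(egfr_annual_slope(dates + 37, cr2, 55, "male"),
               egfr_annual_slope(dates, cr2, 55, "male"), tolerance = 1e-12)

  expect_error(egfr_annual_slope(dates[1:3], cr[1:3], 55, "male"),
               "insufficient")
})

make_cohort_csv <- function(rows, path) {
  readr::write_csv(rows, path)
  path
}

base_row <- function(id, exit = "2012-06-01", outcome = "death",
                     n_meas = 4) {
  k <- 6
  dates <- as.character(as.Date("2010-01-01") + seq(0, 700, length.out = k))
  vals <- rep(1.4, k)
  dates[seq_len(k) > n_meas] <- NA
  vals[seq_len(k) > n_meas] <- NA
  out <- tibble::tibble(patient_id = id, center_id = 1, cohort = "derivation",
                        sex = "male", age = 60, diabetes = FALSE,
                        dipstick = 30, egfr_baseline = 40, phosphate = 3.5,
                        enrol_date = "2010-01-01", exit_date = exit,
                        outcome = outcome)
  for (i in 1:k) {
    out[[paste0("cr_date_", i)]] <- dates[i]
    out[[paste0("cr_val_", i)]] <- vals[i]
  }
  out
}

test_that("cohort reading validates records and reports rejections", {
  path <- withr::local_tempfile(fileext = ".csv")
  rows <- dplyr::bind_rows(
    base_row("ok1"), base_row("ok2"), base_row("ok3"))
  make_cohort_csv(rows, path)
  ch <- read_cohort(path)
  expect_s3_class(ch, "ctpirp_cohort")
  expect_equal(nrow(ch), 3)
  expect_equal(nrow(cohort_rejections(ch)), 0)

  rows2 <- dplyr::bind_rows(
    base_row("ok"),
    base_row("few_meas", n_meas = 3),
    base_row("short_fu", exit = "2010-05-01"),
    base_row("bad_out", outcome = "moved_away"))
  make_cohort_csv(rows2, path)
  ch2 <- read_cohort(path)
  expect_equal(ch2$patient_id, "ok")
  rej <- cohort_rejections(ch2)
  expect_equal(nrow(rej), 3)
  expect_match(rej$reason[rej$patient_id == "few_meas"], "insufficient")
  expect_match(rej$reason[rej$patient_id == "short_fu"], "6 months")
  expect_match(rej$reason[rej$patient_id == "bad_out"], "unknown outcome")
})

test_that("non-monotone creatinine dates are rejected", {
  r <- base_row("swap")
  tmp <- r$cr_date_1; r$cr_date_1 <- r$cr_date_2; r$cr_date_2 <- tmp
  path <- withr::local_tempfile(fileext = ".csv")
  make_cohort_csv(r, path)
  ch <- read_cohort(path)
  expect_equal(nrow(ch), 0)
  expect_match(cohort_rejections(ch)$reason, "non-monotone")
})

test_that("derived columns round-trip through write/read", {
  d <- simulate_cohort(30, seed = 5)
  d <- add_derived(d)
  expect_true(all(!is.na(d$egfr_slope)))
  path <- withr::local_tempfile(fileext = ".csv")
  spath <- withr::local_tempfile(fileext = ".csv")
  write_cohort(d, path, spath)
  back <- read_cohort(path, series_path = spath)
  expect_equal(nrow(back), 30)
  expect_equal(back$egfr_baseline, d$egfr_baseline, tolerance = 1e-9)
  expect_equal(nrow(back$creatinine_series[[1]]), 5)
})
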