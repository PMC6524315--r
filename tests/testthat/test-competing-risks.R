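test_that("single-cause CIF reduces to one minus the KM survival", {
  d <- tibble::tibble(time = c(1, 1.5, 2, 3, 4, 5),
                      outcome = c("rrt", "admin_censor", "rrt", "rrt",
                                  "admin_censor", "rrt"))
  cc <- cif_curves(d, causes = "rrt")
  km <- km_curve(d, event = "rrt")
  at <- sort(unique(d$time[d$outcome == "rrt"]))
  expect_equal(cif_at(cc, "rrt", at), 1 - km_surv_at(km, at),
               tolerance = 1e-12)
})

test_that("Aalen-Johansen matches the hand-computed two-cause table", {
  # worked by hand: events A at 1 and 3, B at 2 and 4, censorings at 1.5, 3.5
  # t=1: S(0)=1,    CIF_A = 1/6;             S = 5/6
  # t=2: n=4,       CIF_B = 5/6 * 1/4 = 5/24; S = 5/8
  # t=3: n=3,       CIF_A = 1/6 + 5/8/3 = 3/8; S = 5/12
  # t=4: n=1,       CIF_B = 5/24 + 5/12 = 5/8; S = 0
  d <- tibble::tibble(time = c(1, 1.5, 2, 3, 3.5, 4),
                      outcome = c("rrt", "admin_censor", "death", "rrt",
                                  "admin_censor", "death"))
  cc <- cif_curves(d, causes = c("rrt", "death"))
  expect_equal(cif_at(cc, "rrt", c(1, 2, 3, 4)),
               c(1 / 6, 1 / 6, 3 / 8, 3 / 8), tolerance = 1e-12)
  expect_equal(cif_at(cc, "death", c(1, 2, 3, 4)),
               c(0, 5 / 24, 5 / 24, 5 / 8), tolerance = 1e-12)
  expect_equal(cif_at(cc, "event_free", 4), 0, tolerance = 1e-12)
  # against the independent recursion on random data too
  set.seed(14)
  t2 <- round(runif(60, 0.6, 6), 2)
  o2 <- sample(c("rrt", "death", "lost", "admin_censor"), 60, replace = TRUE)
  cc2 <- cif_curves(tibble::tibble(time = t2, outcome = o2))
  orc <- oracle_aj(t2, o2, c("rrt", "death", "lost"))
  for (k in c("rrt", "death", "lost")) {
    sub <- orc[orc$cause == k, ]
    expect_equal(cif_at(cc2, k, sub$time), sub$cif, tolerance = 1e-12)
  }
})

test_that("cause CIFs and event-free survival conserve probability", {
  for (seed in c(3, 19)) {
    d <- simulate_cohort(400, seed = seed)
    cc <- cif_curves(d)
    tot <- cc |>
      dplyr::group_by(time) |>
      dplyr::summarise(s = sum(cif), .groups = "drop")
    expect_true(all(abs(tot$s - 1) < 1e-10))
  }
})

test_that("CIFs are non-decreasing and bounded", {
  d <- simulate_cohort(500, seed = 23)
  cc <- cif_curves(d)
  for (k in c("rrt", "death", "lost")) {
    ci <- cc$cif[cc$cause == k]
    expect_true(all(diff(ci) >= -1e-12))
    expect_true(all(ci >= 0 & ci <= 1))
  }
})

test_that("unknown cause labels error", {
  d <- tibble::tibble(time = 1, outcome = "vanished")
  expect_error(cif_curves(d), "unknown cause")
  d2 <- simulate_cohort(50, seed = 1)
  expect_error(cif_at(cif_curves(d2), "vanished", 2), "unknown cause")
})

fg_fixture <- function() {
  tibble::tibble(
    time = c(1, 1.5, 2, 2.5, 3, 3.5, 4, 4.5),
    outcome = c("rrt", "death", "admin_censor", "rrt", "death", "rrt",
                "admin_censor", "rrt"),
    x = c(0, 1, 0, 1, 0, 1, 0, 1))
}

test_that("Fine-Gray collapses to cause-specific Cox without competitors", {
  d <- tibble::tibble(
    time = c(1, 1.6, 2.2, 2.9, 3.4, 4.1, 5, 5.6),
    outcome = c("rrt", "rrt", "admin_censor", "rrt", "rrt", "admin_censor",
                "rrt", "admin_censor"),
    x = c(0, 1, 0, 1, 0, 1, 0, 1))
  fg <- fit_fine_gray(d, cause = "rrt", covariates = "x",
                      competing = "rrt", entry_time = 0)
  cx <- fit_cox(d, "x", event = "rrt", entry_time = 0)
  expect_equal(unname(fg$coefficients), unname(cx$coefficients),
               tolerance = 1e-8)
})

test_that("Fine-Gray maximises the explicit IPCW-weighted likelihood", {
  d <- fg_fixture()
  fg <- fit_fine_gray(d, cause = "rrt", covariates = "x",
                      competing = c("rrt", "death"), entry_time = 0)
  b_oracle <- oracle_fg_mle(d$time, d$outcome, d$x, cause = "rrt",
                            competing = c("rrt", "death"),
                            censor_codes = c("admin_censor", "lost"))
  expect_equal(unname(fg$coefficients), b_oracle, tolerance = 1e-4)
})

test_that("subdistribution-parameter recovery hits the known truth", {
  d <- simulate_fg_cohort(2000, beta = log(3.4), seed = 42)
  fg <- fit_fine_gray(d, cause = "rrt", covariates = "x",
                      competing = c("rrt", "death"), entry_time = 0)
  td <- tidy(fg)
  expect_true(td$conf_low < 3.4 & 3.4 < td$conf_high)
})

test_that("fitted one-minus-CIF at reference covariates is non-increasing", {
  d <- simulate_fg_cohort(300, beta = log(2), seed = 5)
  fg <- fit_fine_gray(d, cause = "rrt", covariates = "x",
                      competing = c("rrt", "death"), entry_time = 0)
  sf <- survival::survfit(fg$fit, newdata = data.frame(x = 0))
  expect_true(all(diff(sf$surv) <= 1e-12))
})

test_that("Fine-Gray agrees with an independent implementation", {
  d <- simulate_fg_cohort(800, beta = log(2.5), seed = 9)
  fg <- fit_fine_gray(d, cause = "rrt", covariates = "x",
                      competing = c("rrt", "death"), entry_time = 0)
  fstatus <- ifelse(d$outcome == "rrt", 1,
                    ifelse(d$outcome == "death", 2, 0))
  cr <- cmprsk::crr(d$time, fstatus, cov1 = d$x)
  expect_equal(unname(fg$coefficients), unname(cr$coef), tolerance = 1e-8)
  expect_equal(sqrt(as.numeric(fg$robust_vcov)), sqrt(diag(cr$var)),
               tolerance = 0.02)
})

test_that("absent events of interest error; zero competitors are valid", {
  d <- fg_fixture()
  expect_error(fit_fine_gray(d, cause = "lost", covariates = "x"),
               "no events")
})
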