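test_that("horizon censoring caps times and is idempotent", {
  d <- tibble::tibble(time = c(5.2, 3.9, 4.0),
                      outcome = c("rrt", "death", "rrt"))
  out <- censor_at_horizon(d, 4)
  expect_equal(out$time, c(4, 3.9, 4))
  expect_equal(out$outcome, c("admin_censor", "death", "rrt"))
  expect_identical(censor_at_horizon(out, 4), out)
})

test_that("discrimination separates nodes with different hazards", {
  cfg <- sim_config()
  d <- assign_nodes(simulate_cohort(8000, cfg, seed = 31))
  disc <- discrimination_summary(dplyr::filter(d, node %in% c(1, 3)),
                                 event = "rrt", horizon = 4)
  pair <- disc$pairs[disc$pairs$node_a == 1 & disc$pairs$node_b == 3, ]
  expect_gt(pair$max_separation, 0.4)
  expect_lt(pair$logrank_p, 1e-6)
})

test_that("identically-hazarded nodes show vanishing separation", {
  cfg <- sim_config(risk6_rrt = rep(0.3, 7), risk6_death = rep(0.2, 7))
  d <- assign_nodes(simulate_cohort(6000, cfg, seed = 37))
  disc <- discrimination_summary(dplyr::filter(d, node %in% c(6, 7)),
                                 event = "rrt", horizon = 4)
  expect_lt(disc$pairs$max_separation[1], 0.05)
})

test_that("single-node input errors", {
  d <- assign_nodes(simulate_cohort(200, seed = 2))
  expect_error(discrimination_summary(dplyr::filter(d, node == 7)),
               "two nodes")
})

test_that("self-calibration passes and the reference curve is the baseline", {
  d <- assign_nodes(simulate_cohort(5000, seed = 41))
  dh <- censor_at_horizon(d, 4)
  fit <- fit_cox(dh, "node", event = "rrt")
  cal <- calibration_curves(fit, dh)
  expect_true(all(cal$summary$sup_gap < 0.03))
  expect_false(any(cal$summary$flagged))
  ref <- fit$reference$node
  ref_rows <- cal$curves[cal$curves$node == as.integer(ref), ]
  expect_equal(ref_rows$expected,
               km_surv_at(fit$baseline_survival, ref_rows$time))
})

test_that("an engineered hazard shift in one node is flagged, others pass", {
  two <- make_two_cohorts(n = 5000, seed = 43, multiplier = c("4" = 0.5))
  dh <- censor_at_horizon(two$derivation, 4)
  vh <- censor_at_horizon(two$validation, 4)
  fit <- fit_cox(dh, "node", event = "rrt")
  cal <- calibration_curves(fit, vh)
  expect_true(cal$summary$flagged[cal$summary$node == 4])
  # the engineered node dominates every Monte-Carlo gap
  expect_equal(cal$summary$node[which.max(cal$summary$sup_gap)], 4L)
})

test_that("a node absent from the validation cohort errors", {
  two <- make_two_cohorts(n = 400, seed = 47)
  dh <- censor_at_horizon(two$derivation, 4)
  fit <- fit_cox(dh, "node", event = "rrt")
  expect_error(
    calibration_curves(fit, dplyr::filter(two$validation, node != 3)),
    "absent")
})

test_that("the reference node is the one with the most outcome events", {
  # event-count table mirroring the derivation cohort: deaths peak in node 7,
  # RRT events peak in node 2
  counts_rrt <- c(40, 122, 91, 82, 27, 60, 115)
  counts_death <- c(36, 105, 36, 18, 21, 147, 294)
  rows <- list()
  for (k in 1:7) {
    rows[[k]] <- tibble::tibble(
      node = k,
      outcome = c(rep("rrt", counts_rrt[k]), rep("death", counts_death[k])),
      time = 2)
  }
  d <- dplyr::bind_rows(rows)
  expect_equal(reference_by_events(d, "rrt"), 2)
  expect_equal(reference_by_events(d, "death"), 7)
})

test_that("interaction model picks references automatically and finds an
           engineered validation-only effect", {
  two <- make_two_cohorts(n = 4000, seed = 53,
                          multiplier = c("5" = 0.23))
  both <- dplyr::bind_rows(two$derivation, two$validation)
  fit <- interaction_model(both, event = "rrt", cluster = "center_id",
                           horizon = 4)
  expect_equal(fit$reference_node, 2)
  td <- tidy(fit)
  row <- td[td$term == "node5:cohortvalidation", ]
  expect_lt(row$hazard_ratio, 1)
  expect_lt(row$conf_high, 1)
})

test_that("null interactions cover 1 under identical cohort processes", {
  hits <- 0; total <- 0
  for (s in 1:8) {
    two <- make_two_cohorts(n = 1200, seed = 100 + s)
    both <- dplyr::bind_rows(two$derivation, two$validation)
    fit <- interaction_model(both, event = "death", horizon = 4)
    td <- tidy(fit)
    inter <- td[grepl(":", td$term), ]
    hits <- hits + sum(inter$conf_low <= 1 & 1 <= inter$conf_high)
    total <- total + nrow(inter)
  }
  expect_gte(hits / total, 0.9)
})

test_that("risk ranking follows the published bands and is monotone", {
  expect_equal(as.character(rank_nodes(0.43)), "very low")
  expect_equal(as.character(rank_nodes(2.93)), "very high")
  expect_equal(as.character(rank_nodes(1.0)), "high")
  expect_equal(as.character(rank_nodes(c(0.49, 0.6, 1.7, 2.01))),
               c("very low", "low", "high", "very high"))
  hr <- sort(exp(runif(30, -2, 2)))
  expect_true(all(diff(as.integer(rank_nodes(hr))) >= 0))
  expect_error(rank_nodes(-1), "positive")
})

test_that("goodness-of-fit table has the published degrees of freedom", {
  d <- add_derived(assign_nodes(simulate_cohort(2500, seed = 59)))
  d$node <- d$node_true
  gof <- compare_models(censor_at_horizon(d, 4), event = "death")
  expect_equal(gof$model, c("CT-PIRP nodes", "Baseline CKD-EPI stage",
                            "eGFR progression rate"))
  expect_equal(gof$df[1], 6)
  expect_lte(gof$df[2], 4)
  expect_lte(gof$df[3], 4)
  expect_true(all(gof$bic > gof$aic))
})

test_that("the model matching the data-generating stratification wins", {
  # hazards differ only by node, so the node model should have the best AIC
  d <- add_derived(assign_nodes(simulate_cohort(3000, seed = 61)))
  d$node <- d$node_true
  gof <- compare_models(censor_at_horizon(d, 4), event = "rrt")
  expect_equal(gof$model[which.min(gof$aic)], "CT-PIRP nodes")
})

test_that("incidence rate ratios follow the closed form", {
  expect_equal(incidence_rate_ratio(50, 1000, 50, 1000)$irr, 1)
  out <- incidence_rate_ratio(50, 1000, 25, 1000)
  expect_equal(out$irr, 0.5)
  se <- sqrt(1 / 50 + 1 / 25)
  expect_equal(out$conf_low, exp(log(0.5) - qnorm(0.975) * se))
  expect_equal(out$conf_high, exp(log(0.5) + qnorm(0.975) * se))
  # scale invariance
  expect_equal(incidence_rate_ratio(50, 2000, 25, 2000)$irr, 0.5)
  expect_error(incidence_rate_ratio(0, 100, 0, 100), "zero events")
  expect_error(incidence_rate_ratio(5, 0, 2, 10), "positive")
})
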