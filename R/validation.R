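#' Administrative censoring at a follow-up horizon
#'
#' Events (of any kind) occurring after `horizon` years become administrative
#' censorings at the horizon; earlier records are unchanged. Used to balance
#' follow-up length between enrolment waves (4 years in the validation
#' analyses) and to reduce the influence of long-term survivors. Idempotent.
#'
#' @param data Data frame with `time` and `outcome`.
#' @param horizon Horizon in years; must exceed the entry time.
#' @return The data with `time` capped and `outcome` recoded.
#' @export
censor_at_horizon <- function(data, horizon = 4) {
  if (horizon <= 0) abort("horizon must be positive")
  late <- data$time > horizon
  data$outcome[late] <- "admin_censor"
  data$time[late] <- horizon
  data
}

#' Per-node discrimination summary
#'
#' Computes the outcome-specific Kaplan-Meier curve of every node and, for
#' every node pair, the maximum absolute survival difference over the
#' common follow-up window together with a log-rank test — numerical
#' summaries supporting the visual "well separated curves" criterion.
#'
#' @param data Cohort tibble with `node`, `time`, `outcome`.
#' @param event Outcome of interest.
#' @param entry_time Delayed entry, years.
#' @param horizon Optional horizon applied via [censor_at_horizon()].
#' @return List of class `ctpirp_discrimination`: `curves` (tibble with
#'   `node` + curve columns) and `pairs` (tibble: `node_a`, `node_b`,
#'   `max_separation`, `logrank_chisq`, `logrank_p`).
#' @export
discrimination_summary <- function(data, event = "rrt", entry_time = 0.5,
                                   horizon = NULL) {
  data <- filter(data, !is.na(.data$node))
  if (!is.null(horizon)) data <- censor_at_horizon(data, horizon)
  nodes <- sort(unique(data$node))
  if (length(nodes) < 2) abort("need at least two nodes with subjects")
  status <- as.integer(data$outcome == event)
  with_events <- nodes[vapply(nodes, function(k) {
    sum(status[data$node == k]) > 0
  }, logical(1))]
  skipped <- setdiff(nodes, with_events)
  if (length(skipped) > 0) {
    warn(paste("node(s) with zero events skipped in pairwise tests:",
               paste(skipped, collapse = ", ")))
  }
  curves <- purrr::map_dfr(nodes, function(k) {
    cv <- km_curve(filter(data, .data$node == k), event = event,
                   entry_time = entry_time)
    bind_cols(tibble(node = k), as_tibble(cv))
  })
  grid <- sort(unique(data$time[status == 1]))
  surv_on <- function(k) {
    cv <- curves %>% filter(.data$node == k)
    vapply(grid, function(t) {
      idx <- which(cv$time <= t)
      if (length(idx) == 0) 1 else cv$surv[max(idx)]
    }, numeric(1))
  }
  smat <- vapply(nodes, surv_on, numeric(length(grid)))
  pairs <- purrr::map_dfr(utils::combn(seq_along(nodes), 2,
                                       simplify = FALSE), function(ij) {
    a <- nodes[ij[1]]; b <- nodes[ij[2]]
    sep <- max(abs(smat[, ij[1]] - smat[, ij[2]]))
    sub <- data[data$node %in% c(a, b), ]
    st <- as.integer(sub$outcome == event)
    lr <- tryCatch(survival::survdiff(
      survival::Surv(sub$time, st) ~ factor(sub$node)),
      error = function(e) NULL)
    tibble(node_a = a, node_b = b, max_separation = sep,
           logrank_chisq = if (is.null(lr)) NA_real_ else unname(lr$chisq),
           logrank_p = if (is.null(lr)) NA_real_ else
             pchisq(unname(lr$chisq), df = 1, lower.tail = FALSE))
  })
  structure(list(curves = curves, pairs = pairs, event = event,
                 skipped = skipped),
            class = "ctpirp_discrimination")
}

#' Calibration by baseline-survival transfer
#'
#' The expected survival of node *j* in a new cohort is the derivation
#' cohort's baseline survival raised to `exp(beta_j)` — the population-average
#' prediction under the assumption that baseline survival carries over
#' between enrolment waves. It is compared with the observed Kaplan-Meier of
#' each node in the validation cohort on a half-yearly evaluation grid; a
#' node is flagged miscalibrated when the sup-norm gap over the grid exceeds
#' `flag_threshold` (the published assessment is graphical; the numeric rule
#' makes the criterion testable).
#'
#' @param derivation_fit A `ctpirp_cox` fitted on the derivation cohort with
#'   node indicators as the only predictors.
#' @param validation Validation cohort tibble with `node`, `time`, `outcome`.
#' @param grid Evaluation times in years.
#' @param flag_threshold Sup-gap above which a node is flagged.
#' @return List of class `ctpirp_calibration`: `curves` (node, time,
#'   expected, observed, obs_lower, obs_upper, covered) and `summary` (node,
#'   sup_gap, flagged, coverage — share of grid points where the observed CI
#'   covers the expected value).
#' @export
calibration_curves <- function(derivation_fit, validation,
                               grid = seq(0.5, 4, by = 0.5),
                               flag_threshold = 0.05) {
  validation <- filter(validation, !is.na(.data$node))
  nodes_val <- sort(unique(validation$node))
  fit_nodes <- as.integer(c(derivation_fit$reference[["node"]],
                            sub("^node", "",
                                grep("^node", names(derivation_fit$coefficients),
                                     value = TRUE))))
  missing_nodes <- setdiff(fit_nodes, nodes_val)
  if (length(missing_nodes) > 0) {
    abort(paste("node(s) absent from validation cohort:",
                paste(missing_nodes, collapse = ", ")))
  }
  event <- derivation_fit$event
  curves <- purrr::map_dfr(nodes_val, function(k) {
    exp_curve <- predict_node_survival(derivation_fit, k)
    obs <- km_curve(filter(validation, .data$node == k), event = event,
                    entry_time = derivation_fit$entry_time)
    step_at <- function(cv, col, t, default) {
      idx <- which(cv$time <= t)
      if (length(idx) == 0) default else cv[[col]][max(idx)]
    }
    purrr::map_dfr(grid, function(t) {
      e <- step_at(exp_curve, "surv", t, 1)
      o <- step_at(obs, "surv", t, 1)
      lo <- step_at(obs, "lower", t, NA_real_)
      up <- step_at(obs, "upper", t, NA_real_)
      tibble(node = k, time = t, expected = e, observed = o,
             obs_lower = lo, obs_upper = up,
             covered = !is.na(lo) & !is.na(up) & lo <= e & e <= up)
    })
  })
  summary <- curves %>%
    group_by(.data$node) %>%
    summarise(sup_gap = max(abs(.data$expected - .data$observed)),
              coverage = mean(.data$covered),
              .groups = "drop") %>%
    mutate(flagged = .data$sup_gap > flag_threshold)
  structure(list(curves = curves, summary = summary, event = event,
                 flag_threshold = flag_threshold),
            class = "ctpirp_calibration")
}

#' Node x cohort interaction model
#'
#' Fits the validation model with subgroup membership, the cohort indicator
#' and their interaction as predictors: significant node main effects
#' identify high/low-risk subgroups, a cohort main effect reflects baseline
#' heterogeneity, and null interactions indicate that subgroup effects are
#' consistent across enrolment waves. The reference node is the node with the
#' largest number of events of the outcome (overridable); the derivation
#' cohort is the reference cohort. Standard errors are cluster-robust by
#' nephrology unit when `cluster` is given.
#'
#' @param data Combined cohort tibble (both values of `cohort` present) with
#'   `node`, `time`, `outcome`.
#' @param event Outcome of interest.
#' @param model `"cox"` (cause-specific) or `"fine_gray"`.
#' @param reference_node `"auto"` (largest event count) or a node label.
#' @param cluster Cluster column name (e.g. `"center_id"`).
#' @param horizon Optional horizon (years) applied first.
#' @param entry_time Delayed entry, years.
#' @return A `ctpirp_cox` or `ctpirp_fg` fit with attributes
#'   `reference_node`; empty node-by-cohort cells are reported via a warning.
#' @export
interaction_model <- function(data, event = "rrt",
                              model = c("cox", "fine_gray"),
                              reference_node = "auto", cluster = NULL,
                              horizon = NULL, entry_time = 0.5) {
  model <- match.arg(model)
  data <- filter(data, !is.na(.data$node))
  if (!is.null(horizon)) data <- censor_at_horizon(data, horizon)
  if (length(unique(data$cohort)) < 2) {
    abort("both cohorts must be present")
  }
  ref <- if (identical(reference_node, "auto")) {
    reference_by_events(data, event)
  } else as.integer(reference_node)
  cells <- tidyr::expand_grid(node = sort(unique(data$node)),
                              cohort = unique(data$cohort)) %>%
    dplyr::anti_join(distinct(data, .data$node, .data$cohort),
                     by = c("node", "cohort"))
  if (nrow(cells) > 0) {
    warn(paste0("empty node x cohort cell(s): ",
                paste(paste0("node ", cells$node, "/", cells$cohort),
                      collapse = ", ")))
  }
  data$node <- stats::relevel(factor(data$node), ref = as.character(ref))
  data$cohort <- factor(data$cohort,
                        levels = c("derivation", "validation"))
  fit <- if (model == "cox") {
    fit_cox(data, "node * cohort", event = event, cluster = cluster,
            entry_time = entry_time)
  } else {
    fit_fine_gray(data, cause = event, covariates = "node * cohort",
                  cluster = cluster, entry_time = entry_time)
  }
  fit$reference_node <- ref
  fit
}

#' Reference node by outcome event count
#'
#' @param data Cohort tibble with `node` and `outcome`.
#' @param event Outcome of interest.
#' @return The node label with the most events (smallest label on ties).
#' @export
reference_by_events <- function(data, event) {
  counts <- data %>%
    filter(.data$outcome == event, !is.na(.data$node)) %>%
    count(.data$node)
  if (nrow(counts) == 0) abort("no events of the given type")
  counts$node[which.max(counts$n)]
}

#' Qualitative risk ranking of hazard ratios
#'
#' Maps node hazard ratios to the four-band qualitative ranking: very low
#' risk up to 0.5, low risk in (0.5, 0.8\], high risk in (0.8, 2\] and very
#' high risk above 2. (The published band list leaves (1.5, 2\] unnamed; it
#' is mapped to "high" since only an HR of 2.93 is annotated "very high".)
#'
#' @param hr Positive hazard ratios (vector, possibly named by node).
#' @return Ordered factor `very low < low < high < very high`.
#' @export
rank_nodes <- function(hr) {
  if (any(!is.finite(hr) | hr <= 0)) abort("hazard ratios must be positive")
  cut(hr, breaks = c(0, 0.5, 0.8, 2, Inf),
      labels = c("very low", "low", "high", "very high"),
      right = TRUE, ordered_result = TRUE)
}

#' Goodness-of-fit comparison of univariate stratification models
#'
#' Fits three univariate Cox models for the outcome — CT-PIRP node (6 df),
#' baseline CKD stage (4 df) and annual eGFR-progression category (4 df) —
#' and reports AIC/BIC, lower is better. Progression categories default to
#' five bands of the annual slope (mL/min/1.73 m^2 per year):
#' `<= -5`, `(-5, -3]`, `(-3, -1]`, `(-1, 1]`, `> 1`.
#'
#' @param data Cohort tibble with `node`, `egfr_baseline` (or `ckd_stage`)
#'   and `egfr_slope` columns.
#' @param event Outcome of interest.
#' @param entry_time Delayed entry, years.
#' @param slope_breaks Interior break points of the progression bands.
#' @return Tibble: `model`, `df`, `loglik`, `aic`, `bic`, ordered as fitted.
#' @export
compare_models <- function(data, event = "rrt", entry_time = 0.5,
                           slope_breaks = c(-5, -3, -1, 1)) {
  data <- filter(data, !is.na(.data$node), !is.na(.data$egfr_slope))
  if (!"ckd_stage" %in% names(data)) {
    data$ckd_stage <- ckd_stage(data$egfr_baseline)
  }
  data$slope_cat <- cut(data$egfr_slope,
                        breaks = c(-Inf, slope_breaks, Inf), right = TRUE)
  one <- function(var, label) {
    x <- droplevels(factor(data[[var]]))
    used <- levels(x)
    has_events <- vapply(used, function(l) {
      any(data$outcome[x == l] == event)
    }, logical(1))
    if (any(!has_events)) {
      warn(paste0(label, ": category with zero events collapsed into ",
                  "neighbouring level: ",
                  paste(used[!has_events], collapse = ", ")))
      # merge empty categories into the adjacent lower level
      for (i in which(!has_events)) {
        tgt <- if (i > 1) used[i - 1] else used[min(which(has_events))]
        levels(x)[levels(x) == used[i]] <- tgt
      }
    }
    data$.gof_var <- droplevels(x)
    fit <- fit_cox(data, ".gof_var", event = event, entry_time = entry_time)
    tibble(model = label, df = fit$df, loglik = fit$loglik,
           aic = fit$aic, bic = fit$bic)
  }
  bind_rows(one("node", "CT-PIRP nodes"),
            one("ckd_stage", "Baseline CKD-EPI stage"),
            one("slope_cat", "eGFR progression rate"))
}

#' Incidence rate ratio between two groups
#'
#' `IRR = rate_b / rate_a` with the standard log-scale Wald interval
#' `exp(log IRR +/- z * sqrt(1/events_a + 1/events_b))`.
#'
#' @param events_a,events_b Event counts.
#' @param persontime_a,persontime_b Person-time at risk (same units).
#' @param conf_level Confidence level.
#' @return Tibble: `irr`, `conf_low`, `conf_high`, `rate_a`, `rate_b`.
#' @export
incidence_rate_ratio <- function(events_a, persontime_a,
                                 events_b, persontime_b,
                                 conf_level = 0.95) {
  if (persontime_a <= 0 || persontime_b <= 0) {
    abort("person-time must be positive")
  }
  if (events_a + events_b == 0) abort("zero events in both groups")
  rate_a <- events_a / persontime_a
  rate_b <- events_b / persontime_b
  irr <- rate_b / rate_a
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(1 / events_a + 1 / events_b)
  tibble(irr = irr, conf_low = exp(log(irr) - z * se),
         conf_high = exp(log(irr) + z * se),
         rate_a = rate_a, rate_b = rate_b)
}
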