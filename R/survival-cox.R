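#' Cause-specific Cox proportional hazards model
#'
#' Fits a Cox model for one outcome (other terminal outcomes censored), with
#' delayed entry at `entry_time`, Breslow tie handling by default, and a
#' cluster-robust sandwich covariance alongside the model-based one. The
#' baseline survival function at the reference covariate pattern (first
#' factor levels, zero for numeric covariates) is computed from the Breslow
#' cumulative-hazard estimator.
#'
#' @param data Data frame with `time`, `outcome` and the covariate columns.
#'   Character covariates are coerced to factors.
#' @param covariates Character vector of covariate names, or a one-sided
#'   formula right-hand side as a string (interactions allowed, e.g.
#'   `"node * cohort"`).
#' @param event Outcome of interest.
#' @param cluster Optional column name defining clusters (e.g. nephrology
#'   unit) for the sandwich variance; with `NULL` each subject is its own
#'   cluster and the sandwich reduces to the standard robust (score-residual)
#'   covariance.
#' @param entry_time Delayed-entry time in years.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return An object of class `ctpirp_cox`; see [tidy.ctpirp_cox()] and
#'   [glance.ctpirp_cox()].
#' @export
fit_cox <- function(data, covariates, event = "rrt", cluster = NULL,
                    entry_time = 0.5, ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  event <- match.arg(event, outcome_levels())
  data <- as_tibble(data)
  if (sum(data$outcome == event) < 1) abort("no events of the given type")
  vars <- all.vars(as.formula(paste("~", paste(covariates, collapse = "+"))))
  for (v in vars) {
    # node labels are categorical even when stored as integers
    if (is.character(data[[v]]) || v == "node") {
      data[[v]] <- factor(data[[v]])
    }
  }
  data$.status <- as.integer(data$outcome == event)
  data$.entry <- entry_time
  rhs <- paste(covariates, collapse = " + ")
  fml <- as.formula(paste("survival::Surv(.entry, time, .status) ~", rhs))
  # with no clustering column every subject is its own cluster, giving the
  # standard score-residual robust covariance
  cl_vec <- if (!is.null(cluster)) data[[cluster]] else seq_len(nrow(data))

  mono <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = ties, x = TRUE, model = TRUE,
                    robust = TRUE, cluster = cl_vec),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w))) {
        mono <<- TRUE
        warn(paste("possible monotone likelihood (complete separation):",
                   conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    })

  base <- baseline_pattern(data, vars)
  sf <- survival::survfit(fit, newdata = base, stype = 2, ctype = 1,
                          conf.type = "log-log")
  baseline <- structure(
    tibble(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
           n_censor = sf$n.censor, surv = as.numeric(sf$surv),
           std_err = as.numeric(sf$std.err),
           lower = as.numeric(sf$lower), upper = as.numeric(sf$upper)),
    class = c("ctpirp_km", "tbl_df", "tbl", "data.frame"),
    event = event, entry_time = entry_time,
    n = fit$n, n_events = fit$nevent)

  df <- length(coef(fit))
  ll <- fit$loglik[length(fit$loglik)]
  structure(list(
    fit = fit,
    coefficients = coef(fit),
    hazard_ratios = exp(coef(fit)),
    model_vcov = fit$naive.var %||% fit$var,
    robust_vcov = fit$var,
    baseline_survival = baseline,
    reference = purrr::map(setNames(vars, vars), function(v) {
      if (is.factor(data[[v]])) levels(data[[v]])[1] else 0
    }),
    loglik = ll, df = df, n = fit$n, n_events = fit$nevent,
    aic = -2 * ll + 2 * df,
    bic = -2 * ll + log(max(fit$nevent, 1)) * df,
    event = event, entry_time = entry_time, ties = ties,
    cluster = cluster, monotone_likelihood = mono
  ), class = "ctpirp_cox")
}

baseline_pattern <- function(data, vars) {
  row <- purrr::map(setNames(vars, vars), function(v) {
    x <- data[[v]]
    if (is.factor(x)) factor(levels(x)[1], levels = levels(x))
    else if (is.logical(x)) FALSE
    else 0
  })
  as_tibble(row)
}

#' Survival curve for one node from a node-indicator Cox fit
#'
#' Under proportional hazards the survival of node *j* is
#' `S0(t)^exp(beta_j)`, with `beta = 0` for the reference node. This is the
#' baseline-survival transfer used for calibration.
#'
#' @param fit A `ctpirp_cox` fitted with a `node` factor among its
#'   predictors.
#' @param node Node label (integer or string matching a factor level).
#' @return A `ctpirp_km`-classed tibble with `time` and `surv`.
#' @export
predict_node_survival <- function(fit, node) {
  beta <- node_coefficient(fit, node)
  out <- fit$baseline_survival
  out$surv <- out$surv^exp(beta)
  out$std_err <- NA_real_
  out$lower <- NA_real_
  out$upper <- NA_real_
  out
}

node_coefficient <- function(fit, node) {
  ref <- fit$reference[["node"]]
  if (is.null(ref)) abort("fit does not contain a 'node' term")
  node <- as.character(node)
  if (node == as.character(ref)) return(0)
  nm <- paste0("node", node)
  if (!nm %in% names(fit$coefficients)) {
    abort(paste0("no coefficient for node ", node))
  }
  unname(fit$coefficients[nm])
}

#' Information criteria of a Cox fit
#'
#' `AIC = -2 loglik + 2 df`; `BIC = -2 loglik + log(d) df` with `d` the
#' number of events (the usual effective sample size for partial-likelihood
#' models).
#'
#' @param fit A `ctpirp_cox` or `ctpirp_fg` object.
#' @return Tibble with `df`, `loglik`, `aic`, `bic`.
#' @export
information_criteria <- function(fit) {
  tibble(df = fit$df, loglik = fit$loglik, aic = fit$aic, bic = fit$bic)
}

cox_tidy_table <- function(x, conf_level = 0.95) {
  est <- x$coefficients
  se_model <- sqrt(diag(as.matrix(x$model_vcov)))
  se_robust <- sqrt(diag(as.matrix(x$robust_vcov)))
  z <- est / se_robust
  q <- qnorm(1 - (1 - conf_level) / 2)
  tibble(term = names(est), estimate = unname(est),
         hazard_ratio = exp(unname(est)),
         std_error = unname(se_model), robust_se = unname(se_robust),
         statistic = unname(z), p_value = 2 * pnorm(-abs(unname(z))),
         conf_low = exp(unname(est - q * se_robust)),
         conf_high = exp(unname(est + q * se_robust)))
}

#' Tidy a Cox fit
#'
#' One row per coefficient, on the log-hazard scale with hazard ratios and
#' robust (sandwich) confidence intervals alongside.
#'
#' @param x A `ctpirp_cox` object.
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @method tidy ctpirp_cox
#' @export
tidy.ctpirp_cox <- function(x, conf_level = 0.95, ...) {
  cox_tidy_table(x, conf_level)
}

#' @method glance ctpirp_cox
#' @export
glance.ctpirp_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, df = x$df, loglik = x$loglik,
         aic = x$aic, bic = x$bic, ties = x$ties,
         cluster = x$cluster %||% NA_character_)
}

#' @export
print.ctpirp_cox <- function(x, ...) {
  cat("Cause-specific Cox model (event:", x$event, "| ties:", x$ties,
      if (!is.null(x$cluster)) paste("| cluster:", x$cluster), ")\n")
  print(tidy(x), ...)
  invisible(x)
}
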