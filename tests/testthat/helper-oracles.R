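# Independent oracles, coded from the textbook definitions, never from the
# package's implementation path.

# product-limit estimator by direct recursion (no ties assumed handled:
# d/n computed per distinct time)
oracle_km <- function(time, status) {
  ts <- sort(unique(time[status == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & status == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Aalen-Johansen CIFs: CIF_k(t) = sum_{t_i <= t} S(t_i-) d_k(t_i) / n(t_i)
oracle_aj <- function(time, cause, causes) {
  ev_times <- sort(unique(time[cause %in% causes]))
  s_minus <- 1
  cif <- setNames(rep(0, length(causes)), causes)
  rows <- list()
  for (t in ev_times) {
    n_risk <- sum(time >= t)
    d_all <- sum(time == t & cause %in% causes)
    for (k in causes) {
      d_k <- sum(time == t & cause == k)
      cif[k] <- cif[k] + s_minus * d_k / n_risk
    }
    s_minus <- s_minus * (1 - d_all / n_risk)
    rows[[length(rows) + 1]] <-
      data.frame(time = t, cause = causes, cif = unname(cif[causes]),
                 surv = s_minus)
  }
  do.call(rbind, rows)
}

# explicit Breslow partial log-likelihood for a single covariate vector,
# delayed entry supported
oracle_cox_loglik <- function(beta, time, status, x, entry = 0) {
  ll <- 0
  for (i in which(status == 1)) {
    at_risk <- time >= time[i] & entry < time[i]
    ll <- ll + x[i] * beta - log(sum(exp(x[at_risk] * beta)))
  }
  ll
}

oracle_cox_mle <- function(time, status, x, entry = 0,
                           interval = c(-8, 8)) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, status, x, entry),
                  interval = interval, maximum = TRUE,
                  tol = 1e-10)$maximum
}

# right-continuous Kaplan-Meier of the censoring distribution
oracle_censor_km <- function(time, is_censor) {
  one <- function(t) {
    g <- 1
    for (c_t in sort(unique(time[is_censor]))) {
      if (c_t <= t) {
        g <- g * (1 - sum(time == c_t & is_censor) / sum(time >= c_t))
      }
    }
    g
  }
  function(t) vapply(t, one, numeric(1))
}

# explicit IPCW-weighted (Geskus) partial log-likelihood of the Fine-Gray
# model: subjects failing from a competing cause stay in risk sets with
# weight G(t)/G(s); censored subjects leave at their censoring time
oracle_fg_loglik <- function(beta, time, outcome, x, cause,
                             competing, censor_codes) {
  G <- oracle_censor_km(time, outcome %in% censor_codes)
  ev <- which(outcome == cause)
  ll <- 0
  for (i in ev) {
    t_i <- time[i]
    w <- numeric(length(time))
    still <- time >= t_i
    w[still] <- 1
    comp <- outcome %in% setdiff(competing, cause) & time < t_i
    w[comp] <- G(t_i) / G(time[comp])
    ll <- ll + x[i] * beta - log(sum(w * exp(x * beta)))
  }
  ll
}

oracle_fg_mle <- function(time, outcome, x, cause = "rrt",
                          competing = c("rrt", "death"),
                          censor_codes = c("admin_censor", "lost"),
                          interval = c(-8, 8)) {
  stats::optimize(function(b) {
    oracle_fg_loglik(b, time, outcome, x, cause, competing, censor_codes)
  }, interval = interval, maximum = TRUE, tol = 1e-10)$maximum
}

# Lin-Wei robust covariance oracle for a single-covariate Cox model without
# ties: V = I^-1 (sum_i U_i U_i') I^-1 with U_i the score residuals
oracle_cox_robust_var <- function(beta, time, status, x) {
  s0 <- function(t) sum(exp(x[time >= t] * beta))
  s1 <- function(t) sum((x * exp(x * beta))[time >= t])
  xbar <- function(t) s1(t) / s0(t)
  ev_times <- time[status == 1]
  n <- length(time)
  U <- numeric(n)
  for (i in seq_len(n)) {
    U[i] <- status[i] * (x[i] - xbar(time[i]))
    for (t in ev_times[ev_times <= time[i]]) {
      U[i] <- U[i] - exp(x[i] * beta) * (x[i] - xbar(t)) / s0(t)
    }
  }
  # observed information: sum over events of S2/S0 - (S1/S0)^2
  s2 <- function(t) sum((x^2 * exp(x * beta))[time >= t])
  info <- sum(vapply(ev_times, function(t) {
    s2(t) / s0(t) - (s1(t) / s0(t))^2
  }, numeric(1)))
  sum(U^2) / info^2
}

# closed-form OLS slope
oracle_ols_slope <- function(t, y) {
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

# exhaustive Mann-Whitney: U as the count of (a_i > b_j) + 0.5 ties, with
# tie-corrected normal moments computed from first principles
oracle_mw_z <- function(a, b) {
  u <- 0
  for (ai in a) for (bj in b) {
    u <- u + (ai > bj) + 0.5 * (ai == bj)
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  pooled <- c(a, b)
  ties <- table(pooled)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  (u - mu) / sqrt(sigma2)
}

# direct Pearson chi-square from the definition
oracle_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# small simulated two-cohort pair used in several validation tests
make_two_cohorts <- function(n = 1200, seed = 7, multiplier = NULL) {
  der <- ctpirp::simulate_cohort(n, seed = seed, cohort = "derivation",
                                 id_prefix = "D")
  val <- ctpirp::simulate_cohort(n, seed = seed + 1000,
                                 cohort = "validation",
                                 hazard_multiplier = multiplier,
                                 id_prefix = "V")
  der$node <- der$node_true
  val$node <- val$node_true
  list(derivation = der, validation = val)
}
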