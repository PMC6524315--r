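#' Pearson chi-square test for a 2x2 table
#'
#' Uncorrected Pearson `X^2 = sum (O - E)^2 / E` by default, with the
#' Yates continuity correction available; p-value from the chi-square
#' distribution with 1 degree of freedom.
#'
#' @param table A 2x2 matrix of counts, or a length-4 vector `(a, b, c, d)`
#'   read row-wise (row = cohort, column = trait present/absent).
#' @param correct Apply the Yates continuity correction.
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  if (!is.matrix(table)) {
    if (length(table) != 4) abort("need a 2x2 table or 4 counts")
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (any(table < 0) || any(table != round(table))) {
    abort("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero margin")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}

#' Mann-Whitney rank-sum z statistic
#'
#' Two-sample rank-sum test with tie-corrected normal approximation (no
#' continuity correction), signed so that `z > 0` when sample `a` is located
#' above sample `b` — the convention of the rank-sum z printed in cohort
#' comparison tables.
#'
#' @param a,b Numeric samples (non-empty).
#' @return Tibble: `z`, `p_value` (two-sided), `u` (Mann-Whitney U of sample
#'   `a`).
#' @export
mann_whitney_z <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))
  if (length(unique(c(a, b))) == 1) abort("all values tied across samples")
  r1 <- sum(r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  z <- (u - mu) / sqrt(sigma2)
  tibble(z = z, p_value = 2 * pnorm(-abs(z)), u = u)
}

#' Per-group descriptive summaries
#'
#' Mean, standard deviation, median and interquartile-range width (75th
#' minus 25th percentile, the "median;IQR" table convention) of each
#' variable per group, plus an all-groups row.
#'
#' @param data A cohort tibble.
#' @param vars Character vector of numeric column names to summarise.
#' @param by Grouping column (default `"node"`).
#' @return Tidy tibble: `group`, `variable`, `n`, `mean`, `sd`, `median`,
#'   `iqr`.
#' @export
group_summaries <- function(data, vars, by = "node") {
  data <- filter(as_tibble(data), !is.na(.data[[by]]))
  if (nrow(data) == 0) abort("empty cohort")
  one <- function(d, label) {
    purrr::map_dfr(vars, function(v) {
      x <- d[[v]][!is.na(d[[v]])]
      tibble(group = label, variable = v, n = length(x),
             mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
             median = median(x),
             iqr = unname(diff(quantile(x, c(0.25, 0.75)))))
    })
  }
  groups <- sort(unique(data[[by]]))
  bind_rows(one(data, "all"),
            purrr::map_dfr(groups, function(g) {
              one(filter(data, .data[[by]] == g), as.character(g))
            }))
}
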