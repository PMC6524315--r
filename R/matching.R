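#' Follow-up duration in rounded months
#'
#' `floor(days / 30.4375 + 0.5)` — follow-up between first and last visit,
#' rounded off to whole months.
#'
#' @param enrol_date,exit_date Dates (or vectors coercible to `Date`).
#' @return Integer months.
#' @export
followup_months <- function(enrol_date, exit_date) {
  days <- as.numeric(as.Date(exit_date) - as.Date(enrol_date))
  as.integer(floor(days / 30.4375 + 0.5))
}

#' 1:1 matching of validation to derivation patients
#'
#' Pairs patients across cohorts that share CT-PIRP node membership and
#' follow-up duration rounded to months. Within each (node, month) cell,
#' pairs are formed up to the smaller cell count, walking both sides in
#' sorted patient-id order so the result is deterministic and invariant to
#' input row order. A positive `caliper_months` additionally pairs leftover
#' patients with the nearest available month within the caliper (closest
#' month first, ties toward the shorter follow-up).
#'
#' @param derivation,validation Cohort tibbles with `patient_id`, `node`,
#'   and either a `fu_months` column or `enrol_date`/`exit_date`.
#' @param caliper_months Non-negative integer caliper; 0 = exact matching.
#' @return List of class `ctpirp_match`: `pairs` (tibble `derivation_id`,
#'   `validation_id`, `node`, `months_derivation`, `months_validation`),
#'   `unmatched_derivation`, `unmatched_validation` (patient-id tibbles), and
#'   `match_variables`.
#' @export
match_cohorts <- function(derivation, validation, caliper_months = 0L) {
  prep <- function(d) {
    d <- filter(as_tibble(d), !is.na(.data$node))
    if (!"fu_months" %in% names(d)) {
      d$fu_months <- followup_months(d$enrol_date, d$exit_date)
    }
    d %>%
      select("patient_id", "node", "fu_months") %>%
      arrange(.data$node, .data$fu_months, .data$patient_id)
  }
  der <- prep(derivation)
  val <- prep(validation)

  exact <- dplyr::inner_join(
    der %>% group_by(.data$node, .data$fu_months) %>%
      mutate(.k = row_number()) %>% ungroup(),
    val %>% group_by(.data$node, .data$fu_months) %>%
      mutate(.k = row_number()) %>% ungroup(),
    by = c("node", "fu_months", ".k"),
    suffix = c("_d", "_v"))
  pairs <- exact %>%
    dplyr::transmute(derivation_id = .data$patient_id_d,
                     validation_id = .data$patient_id_v,
                     node = .data$node,
                     months_derivation = .data$fu_months,
                     months_validation = .data$fu_months)

  left_d <- der %>% filter(!.data$patient_id %in% pairs$derivation_id)
  left_v <- val %>% filter(!.data$patient_id %in% pairs$validation_id)
  if (caliper_months > 0 && nrow(left_d) > 0 && nrow(left_v) > 0) {
    for (delta in seq_len(caliper_months)) {
      for (sgn in c(-1L, 1L)) {
        cand <- dplyr::inner_join(
          left_d %>% group_by(.data$node, .data$fu_months) %>%
            mutate(.k = row_number()) %>% ungroup() %>%
            mutate(.target = .data$fu_months + sgn * delta),
          left_v %>% group_by(.data$node, .data$fu_months) %>%
            mutate(.k = row_number()) %>% ungroup(),
          by = c("node", ".target" = "fu_months", ".k"),
          suffix = c("_d", "_v"))
        if (nrow(cand) > 0) {
          pairs <- bind_rows(pairs, cand %>%
            dplyr::transmute(derivation_id = .data$patient_id_d,
                             validation_id = .data$patient_id_v,
                             node = .data$node,
                             months_derivation = .data$fu_months,
                             months_validation = .data$.target))
          left_d <- left_d %>%
            filter(!.data$patient_id %in% pairs$derivation_id)
          left_v <- left_v %>%
            filter(!.data$patient_id %in% pairs$validation_id)
        }
      }
    }
  }
  structure(list(
    pairs = pairs %>% arrange(.data$node, .data$months_derivation,
                              .data$derivation_id),
    unmatched_derivation = left_d %>% select("patient_id", "node",
                                             "fu_months"),
    unmatched_validation = left_v %>% select("patient_id", "node",
                                             "fu_months"),
    match_variables = c("node", "fu_months"),
    caliper_months = caliper_months
  ), class = "ctpirp_match")
}

#' Keep only the matched subjects of both cohorts
#'
#' @param match A `ctpirp_match`.
#' @param derivation,validation The cohorts that were matched.
#' @return Combined tibble of matched patients from both cohorts.
#' @export
matched_cohort <- function(match, derivation, validation) {
  bind_rows(
    filter(as_tibble(derivation),
           .data$patient_id %in% match$pairs$derivation_id),
    filter(as_tibble(validation),
           .data$patient_id %in% match$pairs$validation_id))
}

#' @export
print.ctpirp_match <- function(x, ...) {
  cat("1:1 cohort match on", paste(x$match_variables, collapse = " + "),
      "\n  pairs:", nrow(x$pairs),
      "| unmatched derivation:", nrow(x$unmatched_derivation),
      "| unmatched validation:", nrow(x$unmatched_validation), "\n")
  invisible(x)
}
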