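#' Derive proteinuria status from its three laboratory components
#'
#' Proteinuria is coded as present if any available component exceeds its
#' clinical threshold: dipstick protein > 20 mg/dL, 24-hour urine total
#' protein > 0.3 g/24 h, or microalbuminuria > 20 mg/L. Comparisons are
#' strict; missing components are non-informative. When all three components
#' are missing the status is undeterminable and an error is raised (or `NA`
#' returned, see `na_undeterminable`).
#'
#' @param dipstick Dipstick protein, mg/dL. May contain `NA`.
#' @param protein_24h 24-hour urine total protein, g/24 h. May contain `NA`.
#' @param microalbumin Microalbuminuria, mg/L. May contain `NA`.
#' @param na_undeterminable If `TRUE`, rows with all three components missing
#'   yield `NA` instead of an error (useful when screening whole cohorts).
#' @return Logical vector: `TRUE` if proteinuria is present.
#' @examples
#' derive_proteinuria(25, NA, NA)        # TRUE
#' derive_proteinuria(10, 0.2, 15)       # FALSE
#' derive_proteinuria(NA, 0.31, NA)      # TRUE
#' @export
derive_proteinuria <- function(dipstick = NA_real_, protein_24h = NA_real_,
                               microalbumin = NA_real_,
                               na_undeterminable = FALSE) {
  n <- max(length(dipstick), length(protein_24h), length(microalbumin))
  dipstick <- rep_len(as.numeric(dipstick), n)
  protein_24h <- rep_len(as.numeric(protein_24h), n)
  microalbumin <- rep_len(as.numeric(microalbumin), n)
  all_missing <- is.na(dipstick) & is.na(protein_24h) & is.na(microalbumin)
  if (any(all_missing) && !na_undeterminable) {
    abort(paste0("proteinuria undeterminable: all three components missing ",
                 "for ", sum(all_missing), " record(s)"))
  }
  hit <- function(x, thr) !is.na(x) & x > thr
  out <- hit(dipstick, 20) | hit(protein_24h, 0.3) | hit(microalbumin, 20)
  out[all_missing] <- NA
  out
}

#' Estimated GFR by the CKD-EPI 2009 creatinine equation
#'
#' @param creatinine Serum creatinine, mg/dL (> 0).
#' @param age Age in years (> 0).
#' @param sex `"female"` or `"male"` (recycled).
#' @param black Logical; applies the 1.159 ethnicity coefficient of the
#'   original equation. Defaults to `FALSE` (the coefficient is rarely used
#'   in European cohorts).
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_ckdepi(0.7, 50, "female")
#' @export
egfr_ckdepi <- function(creatinine, age, sex, black = FALSE) {
  if (any(creatinine <= 0, na.rm = TRUE) || any(age <= 0, na.rm = TRUE)) {
    abort("creatinine and age must be positive")
  }
  sex <- match_sex(sex)
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  female <- sex == "female"
  kappa <- if_else(female, 0.7, 0.9)
  alpha <- if_else(female, -0.329, -0.411)
  ratio <- creatinine / kappa
  g <- 141 * pmin(ratio, 1)^alpha * pmax(ratio, 1)^-1.209 * 0.993^age
  g <- g * if_else(female, 1.018, 1)
  if (isTRUE(black)) g <- g * 1.159
  g
}

# Inverse of egfr_ckdepi in creatinine, used when synthesising creatinine
# series from a target eGFR trajectory.
creatinine_from_egfr <- function(egfr, age, sex, black = FALSE) {
  sex <- match_sex(sex)
  female <- sex == "female"
  kappa <- if_else(female, 0.7, 0.9)
  alpha <- if_else(female, -0.329, -0.411)
  base <- 141 * 0.993^age * if_else(female, 1.018, 1) *
    (if (isTRUE(black)) 1.159 else 1)
  # value of the equation at creatinine == kappa separates the two branches
  ratio <- if_else(egfr >= base, (egfr / base)^(1 / alpha),
                   (egfr / base)^(1 / -1.209))
  ratio * kappa
}

match_sex <- function(sex) {
  s <- tolower(as.character(sex))
  s[s %in% c("f", "female")] <- "female"
  s[s %in% c("m", "male")] <- "male"
  if (!all(s %in% c("female", "male"))) {
    abort("sex must be 'female' or 'male'")
  }
  s
}

#' CKD stage from eGFR
#'
#' Five ordered categories on the KDIGO bands, with stages 1 and 2 merged:
#' `>= 60` (stage 1-2), `45-59` (3a), `30-44` (3b), `15-29` (4), `< 15` (5).
#'
#' @param egfr eGFR in mL/min/1.73 m^2 (> 0).
#' @return Ordered factor with levels `1-2 < 3a < 3b < 4 < 5`.
#' @export
ckd_stage <- function(egfr) {
  if (any(egfr <= 0, na.rm = TRUE)) abort("egfr must be positive")
  cut(egfr, breaks = c(Inf, 60, 45, 30, 15, 0) |> rev(),
      labels = c("5", "4", "3b", "3a", "1-2"),
      right = FALSE, ordered_result = TRUE)
}

#' Annual eGFR slope from a creatinine series
#'
#' Recomputes eGFR at each measurement via [egfr_ckdepi()] with the patient's
#' age advanced by the elapsed time, then fits an ordinary-least-squares line
#' of eGFR against time in years.
#'
#' @param dates Measurement dates (`Date` or coercible); at least 4, strictly
#'   increasing.
#' @param creatinine Serum creatinine at each date, mg/dL.
#' @param age Age in years at the first measurement.
#' @param sex `"female"` or `"male"`.
#' @return Slope in mL/min/1.73 m^2 per year.
#' @export
egfr_annual_slope <- function(dates, creatinine, age, sex) {
  dates <- as.Date(dates)
  if (length(dates) < 4) abort("insufficient measurements: need at least 4")
  if (any(diff(as.numeric(dates)) <= 0)) {
    abort("creatinine dates must be strictly increasing")
  }
  t_years <- as.numeric(dates - dates[1]) / 365.25
  if (max(t_years) == 0) abort("degenerate time axis")
  g <- egfr_ckdepi(creatinine, age + t_years, sex)
  unname(coef(lm(g ~ t_years))[2])
}

#' Read a patient-level cohort file
#'
#' Reads a delimited cohort table (one row per patient) and validates it.
#' Expected columns: `patient_id`, `center_id`, `cohort`
#' (`derivation`/`validation`), `sex`, `age`, `diabetes`,
#' `egfr_baseline`, `enrol_date`, `exit_date`, `outcome`
#' (`rrt`/`death`/`lost`/`admin_censor`); optional `dipstick`, `protein_24h`,
#' `microalbumin`, `proteinuria`, `phosphate`. The creatinine series may be
#' supplied as a companion long table (`series`) with columns `patient_id`,
#' `date`, `creatinine`, or as wide columns `cr_date_1..k` / `cr_val_1..k`.
#'
#' @param path Path to the cohort CSV.
#' @param series_path Optional path to the long creatinine-series CSV.
#' @param schema Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(egfr_baseline = "gfr0")`.
#' @return A validated cohort tibble (invalid rows dropped); the tibble
#'   carries a `rejected` attribute with one diagnostic row per rejected
#'   record (see [cohort_rejections()]).
#' @export
read_cohort <- function(path, series_path = NULL, schema = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        abort(paste0("schema column '", schema[[canon]], "' not found"))
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  series <- NULL
  if (!is.null(series_path)) {
    series <- readr::read_csv(series_path, show_col_types = FALSE,
                              progress = FALSE)
  } else if (any(grepl("^cr_date_", names(raw)))) {
    k <- sum(grepl("^cr_date_", names(raw)))
    series <- purrr::map_dfr(seq_len(k), function(i) {
      tibble(patient_id = as.character(raw$patient_id),
             date = as.Date(raw[[paste0("cr_date_", i)]]),
             creatinine = as.numeric(raw[[paste0("cr_val_", i)]]))
    }) %>% filter(!is.na(.data$date))
    raw <- raw %>% select(-dplyr::matches("^cr_(date|val)_"))
  }
  as_cohort(raw, series = series)
}

#' Validate a cohort data frame
#'
#' Coerces types, attaches the creatinine series as a list-column, checks the
#' inclusion invariants (at least 6 months between enrolment and exit, at
#' least four creatinine measurements on strictly increasing dates, positive
#' age and baseline eGFR, known outcome code), and computes follow-up time in
#' years. Rows violating an invariant are removed and reported via the
#' `rejected` attribute.
#'
#' @param data A data frame of patient records (see [read_cohort()]).
#' @param series Optional long data frame (`patient_id`, `date`,
#'   `creatinine`).
#' @return A cohort tibble with class `ctpirp_cohort`.
#' @export
as_cohort <- function(data, series = NULL) {
  data <- as_tibble(data)
  required <- c("patient_id", "sex", "age", "egfr_baseline",
                "enrol_date", "exit_date", "outcome")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data$patient_id <- as.character(data$patient_id)
  data$enrol_date <- as.Date(data$enrol_date)
  data$exit_date <- as.Date(data$exit_date)
  data$outcome <- as.character(data$outcome)
  if (!"center_id" %in% names(data)) data$center_id <- 1L
  if (!"cohort" %in% names(data)) data$cohort <- "derivation"
  if (!"diabetes" %in% names(data)) data$diabetes <- NA
  data$diabetes <- as.logical(data$diabetes)
  for (col in c("dipstick", "protein_24h", "microalbumin", "phosphate")) {
    if (!col %in% names(data)) data[[col]] <- NA_real_
  }
  if (!is.null(series)) {
    series <- as_tibble(series)
    series$patient_id <- as.character(series$patient_id)
    series$date <- as.Date(series$date)
    # input order is preserved: strictly increasing dates are an invariant
    # to validate, not to repair
    nested <- series %>%
      tidyr::nest(creatinine_series = c("date", "creatinine"))
    data <- left_join(data, nested, by = "patient_id")
  }
  if (!"creatinine_series" %in% names(data)) {
    data$creatinine_series <- vector("list", nrow(data))
  }

  reasons <- character(nrow(data))
  note <- function(idx, msg) {
    reasons[idx] <<- if_else(reasons[idx] == "", msg,
                             paste(reasons[idx], msg, sep = "; "))
  }
  bad_sex <- !tolower(data$sex) %in% c("f", "m", "female", "male")
  note(bad_sex, "unknown sex code")
  note(!data$outcome %in% outcome_levels(), "unknown outcome code")
  note(is.na(data$age) | data$age <= 0, "non-positive age")
  note(is.na(data$egfr_baseline) | data$egfr_baseline <= 0,
       "non-positive baseline eGFR")
  fu_days <- as.numeric(data$exit_date - data$enrol_date)
  note(is.na(fu_days) | fu_days < 182.625,
       "follow-up shorter than 6 months")
  n_meas <- purrr::map_int(data$creatinine_series,
                           ~ if (is.null(.x)) 0L else nrow(.x))
  has_series <- n_meas > 0
  note(has_series & n_meas < 4, "insufficient measurements")
  mono <- purrr::map_lgl(data$creatinine_series, function(s) {
    if (is.null(s) || nrow(s) < 2) return(TRUE)
    all(diff(as.numeric(s$date)) > 0)
  })
  note(!mono, "non-monotone creatinine dates")

  keep <- reasons == ""
  rejected <- tibble(patient_id = data$patient_id[!keep],
                     reason = reasons[!keep])
  out <- data[keep, , drop = FALSE]
  out$sex <- match_sex(out$sex)
  out$time <- as.numeric(out$exit_date - out$enrol_date) / 365.25
  class(out) <- c("ctpirp_cohort", class(out))
  attr(out, "rejected") <- rejected
  out
}

#' Rejected-row diagnostics from cohort validation
#'
#' @param cohort A cohort returned by [read_cohort()] or [as_cohort()].
#' @return Tibble with `patient_id` and `reason` per rejected row.
#' @export
cohort_rejections <- function(cohort) {
  attr(cohort, "rejected") %||% tibble(patient_id = character(),
                                       reason = character())
}

#' Append derived clinical variables to a cohort
#'
#' Adds `proteinuria` (from the three components, unless already present),
#' `ckd_stage` (from baseline eGFR) and `egfr_slope` (annual OLS slope of
#' CKD-EPI eGFR over the creatinine series, `NA` where no series is
#' attached).
#'
#' @param cohort A cohort tibble.
#' @return The cohort with derived columns appended.
#' @export
add_derived <- function(cohort) {
  if (!"proteinuria" %in% names(cohort) || all(is.na(cohort$proteinuria))) {
    cohort$proteinuria <- derive_proteinuria(
      cohort$dipstick, cohort$protein_24h, cohort$microalbumin,
      na_undeterminable = TRUE)
  }
  cohort$ckd_stage <- ckd_stage(cohort$egfr_baseline)
  cohort$egfr_slope <- purrr::pmap_dbl(
    list(cohort$creatinine_series, cohort$age, cohort$sex),
    function(s, age, sex) {
      if (is.null(s) || nrow(s) < 4) return(NA_real_)
      egfr_annual_slope(s$date, s$creatinine, age, sex)
    })
  cohort
}

#' Write a cohort (with derived columns) to CSV
#'
#' The creatinine series list-column, if present, is written to a companion
#' long CSV at `series_path`.
#'
#' @param cohort Cohort tibble.
#' @param path Output CSV path.
#' @param series_path Optional path for the long creatinine-series CSV.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, series_path = NULL) {
  flat <- cohort
  if ("creatinine_series" %in% names(flat)) {
    if (!is.null(series_path)) {
      long <- flat %>%
        select("patient_id", "creatinine_series") %>%
        filter(!purrr::map_lgl(.data$creatinine_series, is.null)) %>%
        tidyr::unnest("creatinine_series")
      readr::write_csv(long, series_path)
    }
    flat$creatinine_series <- NULL
  }
  class(flat) <- setdiff(class(flat), "ctpirp_cohort")
  readr::write_csv(flat, path)
  invisible(path)
}
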