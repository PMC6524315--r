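#' Configuration of the CT-PIRP classification tree
#'
#' The tree splits are fixed quantities taken from the published model:
#' proteinuric patients split on baseline eGFR at 33.652 mL/min/1.73 m^2 and,
#' below that, on serum phosphate at 4.3 mg/dL; non-proteinuric patients
#' split on age and then on diabetes (younger branch) or sex (older branch).
#' The published figure does not print the numeric age threshold; 67 years is
#' the default, consistent with the subgroup age distributions, and can be
#' overridden here.
#'
#' @param egfr_split eGFR split, mL/min/1.73 m^2. "<= goes left".
#' @param phosphate_split Serum phosphate split, mg/dL.
#' @param age_split Age split, years.
#' @return A `tree_config` list.
#' @export
tree_config <- function(egfr_split = 33.652, phosphate_split = 4.3,
                        age_split = 67) {
  stopifnot(egfr_split > 0, phosphate_split > 0, age_split > 0)
  structure(list(egfr_split = egfr_split, phosphate_split = phosphate_split,
                 age_split = age_split), class = "tree_config")
}

#' Assign patients to CT-PIRP nodes
#'
#' Applies the fixed seven-node classification tree. All comparisons at
#' internal splits are inclusive on the left branch ("<=" goes left):
#' \describe{
#'   \item{1}{proteinuric, eGFR > `egfr_split`}
#'   \item{2}{proteinuric, eGFR <= `egfr_split`, phosphate <= `phosphate_split`}
#'   \item{3}{proteinuric, eGFR <= `egfr_split`, phosphate > `phosphate_split`}
#'   \item{4}{non-proteinuric, age <= `age_split`, non-diabetic}
#'   \item{5}{non-proteinuric, age <= `age_split`, diabetic}
#'   \item{6}{non-proteinuric, age > `age_split`, female}
#'   \item{7}{non-proteinuric, age > `age_split`, male}
#' }
#' Patients whose proteinuria status is undeterminable, or who need the
#' phosphate split but have missing phosphate, receive `NA` with the reason
#' recorded in `node_reason`; they are reported, never silently dropped.
#'
#' @param cohort A cohort tibble with columns `proteinuria` (or the three
#'   components), `egfr_baseline`, `phosphate`, `age`, `diabetes`, `sex`.
#' @param config A [tree_config()].
#' @return The cohort with integer `node`, character `node_path` (the
#'   predicate path, e.g. `"proteinuria & egfr<=33.652 & po4>4.3"`) and
#'   `node_reason` (`NA` for assigned patients) columns appended.
#' @export
assign_nodes <- function(cohort, config = tree_config()) {
  cohort <- as_tibble(cohort)
  if (!"proteinuria" %in% names(cohort)) {
    cohort$proteinuria <- derive_proteinuria(
      cohort$dipstick %||% NA_real_, cohort$protein_24h %||% NA_real_,
      cohort$microalbumin %||% NA_real_, na_undeterminable = TRUE)
  }
  es <- config$egfr_split; ps <- config$phosphate_split; as_ <- config$age_split
  pr <- cohort$proteinuria
  g <- cohort$egfr_baseline
  p4 <- cohort$phosphate
  age <- cohort$age
  dm <- cohort$diabetes
  male <- match_sex(cohort$sex) == "male"

  node <- rep(NA_integer_, nrow(cohort))
  path <- rep(NA_character_, nrow(cohort))
  reason <- rep(NA_character_, nrow(cohort))

  reason[is.na(pr)] <- "unassignable: proteinuria undeterminable"
  low <- !is.na(pr) & pr & !is.na(g) & g <= es
  need_p4 <- low & is.na(p4)
  reason[need_p4] <- "unassignable: phosphate missing"

  npr0 <- !is.na(pr) & !pr
  reason[npr0 & age <= as_ & is.na(dm)] <- "unassignable: diabetes missing"

  set <- function(idx, k, p) {
    idx[is.na(idx)] <- FALSE
    node[idx] <<- k
    path[idx] <<- p
  }
  set(!is.na(pr) & pr & g > es, 1L,
      paste0("proteinuria & egfr>", es))
  set(low & !is.na(p4) & p4 <= ps, 2L,
      paste0("proteinuria & egfr<=", es, " & po4<=", ps))
  set(low & !is.na(p4) & p4 > ps, 3L,
      paste0("proteinuria & egfr<=", es, " & po4>", ps))
  npr <- !is.na(pr) & !pr
  set(npr & age <= as_ & !dm, 4L,
      paste0("no proteinuria & age<=", as_, " & no diabetes"))
  set(npr & age <= as_ & dm, 5L,
      paste0("no proteinuria & age<=", as_, " & diabetes"))
  set(npr & age > as_ & !male, 6L,
      paste0("no proteinuria & age>", as_, " & female"))
  set(npr & age > as_ & male, 7L,
      paste0("no proteinuria & age>", as_, " & male"))

  cohort$node <- node
  cohort$node_path <- path
  cohort$node_reason <- reason
  cohort
}

#' Node-assignment report for a whole cohort
#'
#' @param cohort A cohort tibble; [assign_nodes()] is applied if the `node`
#'   column is absent.
#' @param config A [tree_config()].
#' @return A list with `counts` (tibble: node, n, proportion over assigned
#'   patients) and `unassignable` (tibble: patient_id, reason).
#' @export
assignment_report <- function(cohort, config = tree_config()) {
  if (nrow(cohort) == 0) abort("empty cohort")
  if (!"node" %in% names(cohort)) cohort <- assign_nodes(cohort, config)
  assigned <- filter(cohort, !is.na(.data$node))
  counts <- assigned %>%
    count(node = factor(.data$node, levels = 1:7), .drop = FALSE,
          name = "n") %>%
    mutate(node = as.integer(as.character(.data$node)),
           proportion = .data$n / sum(.data$n))
  unassignable <- cohort %>%
    filter(is.na(.data$node)) %>%
    select("patient_id", reason = "node_reason")
  list(counts = counts, unassignable = unassignable)
}
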