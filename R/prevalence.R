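#' Multimorbidity flags
#'
#' A participant is multimorbid when at least two of the 26 registered
#' conditions are present.
#'
#' @param matrix A `disease_matrix`.
#' @return Integer 0/1 vector, one entry per participant, named by
#'   participant id.
#' @export
multimorbid_flags <- function(matrix) {
  stopifnot(inherits(matrix, "disease_matrix"))
  stats::setNames(as.integer(rowSums(matrix) >= 2L), rownames(matrix))
}

# Resolve a covariate name to per-participant values. Derived covariates
# (age bands, BMI class, central obesity, sleep bands) are computed on the
# fly; everything else is read from the record columns.
covariate_values <- function(cohort, name) {
  rec <- cohort$records
  switch(name,
    age_band       = band(rec$age, "age_table1"),
    age_group      = band(rec$age, "age_subgroup"),
    sleep_band     = band(rec$sleep_hours, "sleep"),
    bmi_class      = bmi_class(rec$height_cm, rec$weight_kg),
    central_obesity = central_obesity(rec$waist_cm, rec$sex),
    {
      if (!name %in% names(rec)) {
        stop("unknown covariate '", name, "'", call. = FALSE)
      }
      as.character(rec[[name]])
    }
  )
}

#' Stratified prevalence table
#'
#' Tabulates a binary outcome overall and within each level of the
#' requested covariates, in the style of survey characteristics tables:
#' within a covariate level, the percentage is of outcome-positive
#' participants among that level. Participants missing a covariate are
#' excluded from that covariate's rows only (never from the overall row or
#' the disease analyses). Percentages are rounded half away from zero to
#' one decimal.
#'
#' Derived covariates `age_band` (<45 / 45-64 / >=65), `age_group`
#' (<60 / >=60), `sleep_band`, `bmi_class` and `central_obesity` are
#' available alongside the record columns.
#'
#' @param flags Binary outcome vector aligned to the cohort rows (e.g.
#'   [multimorbid_flags()] or [pattern_flags()]).
#' @param cohort The `cohort` the flags were computed from.
#' @param covariates Character vector of covariate names to stratify by.
#' @param outcome_name Label stored in the table.
#' @return A tibble with columns `outcome`, `covariate`, `level`,
#'   `n_total`, `n_positive`, `pct`; the first row is the overall stratum.
#' @export
prevalence_table <- function(flags, cohort,
                             covariates = c("sex", "age_band"),
                             outcome_name = "multimorbidity") {
  stopifnot(inherits(cohort, "cohort"),
            length(flags) == cohort_size(cohort))
  flags <- as.integer(flags)
  rows <- list(tibble::tibble(
    outcome = outcome_name, covariate = "overall", level = "overall",
    n_total = length(flags), n_positive = sum(flags),
    pct = pct_of(sum(flags), length(flags))
  ))
  for (cov in covariates) {
    values <- covariate_values(cohort, cov)
    keep <- !is.na(values)
    tab <- tibble::tibble(level = values[keep], flag = flags[keep])
    agg <- dplyr::summarise(dplyr::group_by(tab, .data$level),
                            n_total = dplyr::n(),
                            n_positive = sum(.data$flag), .groups = "drop")
    agg <- dplyr::arrange(agg, .data$level)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      outcome = outcome_name, covariate = cov, level = agg$level,
      n_total = agg$n_total, n_positive = agg$n_positive,
      pct = pct_of(agg$n_positive, agg$n_total)
    )
  }
  dplyr::bind_rows(rows)
}

#' Distribution of per-participant condition counts
#'
#' @param matrix A `disease_matrix`.
#' @return Tibble with columns `n_conditions` (0..26) and `n_participants`;
#'   counts sum to the number of participants. Bins with zero participants
#'   are retained up to the observed maximum.
#' @export
condition_count_distribution <- function(matrix) {
  stopifnot(inherits(matrix, "disease_matrix"))
  counts <- rowSums(matrix)
  tab <- tabulate(counts + 1L, nbins = max(counts) + 1L)
  tibble::tibble(n_conditions = seq_along(tab) - 1L, n_participants = tab)
}
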