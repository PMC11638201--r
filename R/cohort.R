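#' @importFrom rlang .data
NULL

# Covariate levels accepted by the validator. Covariates other than
# sex/age/disease flags may be missing (NA); they are never imputed.
covariate_levels <- function() {
  list(
    sex        = c("male", "female"),
    urbanicity = c("rural", "urban"),
    ethnicity  = c("han", "uygur", "kazak", "hui", "tibetan", "other"),
    education  = c("no_formal", "primary", "middle", "college"),
    occupation = c("unemployed", "agriculture", "employed"),
    marital    = c("married", "widowed", "separated_divorced",
                   "never_married"),
    smoking    = c("never", "former", "current"),
    drinking   = c("never", "occasional", "usual"),
    pa_tertile = c("low", "moderate", "high")
  )
}

mandatory_columns <- function() {
  c("participant_id", "sbp", "dbp", "self_reported_hypertension",
    disease_codes(include_hypertension = FALSE), "sex", "age")
}

optional_columns <- function() {
  c("province", "urbanicity", "ethnicity", "education", "occupation",
    "marital", "wealth_tertile", "smoking", "drinking", "pa_tertile",
    "sleep_hours", "height_cm", "weight_kg", "waist_cm")
}

#' Construct a cohort
#'
#' A cohort bundles one-row-per-participant records with the disease
#' registry that fixes condition order for all downstream matrices. The
#' hypertension column of the disease matrix is *derived* later (from
#' measured blood pressure plus the self-report flag under a named
#' criterion); records carry only the 25 questionnaire conditions plus the
#' raw ingredients.
#'
#' @param records Data frame with the columns documented in
#'   `system.file("extdata", "cohort_schema.json", package = "morbclust")`:
#'   `participant_id`, `sbp`, `dbp`, `self_reported_hypertension`, one
#'   logical column per questionnaire condition, `sex`, `age`, and optional
#'   covariates.
#' @param registry Disease registry tibble; defaults to [disease_registry()].
#' @return An object of class `cohort`: a list with elements `records`
#'   (tibble) and `registry`.
#' @export
new_cohort <- function(records, registry = disease_registry()) {
  records <- tibble::as_tibble(records)
  stopifnot(nrow(registry) == 26L, !anyDuplicated(registry$code))
  missing_cols <- setdiff(mandatory_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("cohort records lack mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(records$participant_id)) {
    stop("participant_id values must be unique within a cohort",
         call. = FALSE)
  }
  flag_cols <- c("self_reported_hypertension",
                 disease_codes(include_hypertension = FALSE))
  for (col in flag_cols) {
    records[[col]] <- as.logical(records[[col]])
    if (anyNA(records[[col]])) {
      stop("disease flag column '", col, "' contains missing values",
           call. = FALSE)
    }
  }
  # fill optional covariates absent from the source with explicit typed NA
  numeric_optional <- c("wealth_tertile", "sleep_hours", "height_cm",
                        "weight_kg", "waist_cm")
  for (col in optional_columns()) {
    if (!col %in% names(records)) {
      records[[col]] <- if (col %in% numeric_optional) NA_real_ else
        NA_character_
    }
  }
  records <- records[, c(mandatory_columns(), optional_columns())]
  structure(list(records = records, registry = registry), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d registered conditions\n",
              nrow(x$records), nrow(x$registry)))
  invisible(x)
}

#' Number of participants in a cohort
#' @param x A `cohort`.
#' @return Integer count.
#' @export
cohort_size <- function(x) {
  stopifnot(inherits(x, "cohort"))
  nrow(x$records)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes")] <- TRUE
  out[v %in% c("0", "false", "no")] <- FALSE
  out
}

validate_rows <- function(records) {
  problems <- character(0)
  note <- function(rows, what) {
    if (length(rows) > 0) {
      sprintf("row %d: %s", rows, what)
    } else {
      character(0)
    }
  }
  bad_bp  <- which(!is.finite(records$sbp) | !is.finite(records$dbp) |
                     records$sbp <= 0 | records$dbp <= 0)
  bad_ord <- which(is.finite(records$sbp) & is.finite(records$dbp) &
                     records$dbp >= records$sbp)
  bad_sex <- which(!records$sex %in% covariate_levels()$sex)
  bad_age <- which(!is.finite(records$age) | records$age < 0)
  flag_cols <- c("self_reported_hypertension",
                 disease_codes(include_hypertension = FALSE))
  bad_flag <- which(Reduce(`|`, lapply(records[flag_cols], is.na)))
  problems <- c(
    note(bad_bp, "blood pressure missing, non-numeric or non-positive"),
    note(bad_ord, "diastolic pressure not below systolic"),
    note(bad_sex, "sex not one of male/female"),
    note(bad_age, "age missing or negative"),
    note(bad_flag, "unparseable disease flag")
  )
  bad_rows <- sort(unique(c(bad_bp, bad_ord, bad_sex, bad_age, bad_flag)))
  list(bad_rows = bad_rows, problems = problems)
}

#' Read a cohort from CSV
#'
#' Reads a comma-separated, UTF-8, "."-decimal file with a header row.
#' Boolean columns accept 0/1, true/false and yes/no (case-insensitive).
#' Rows violating record invariants (non-positive or non-numeric blood
#' pressure, diastolic >= systolic, unknown sex, unparseable flags) are
#' rejected with a warning listing the offending data rows; the remaining
#' rows form the returned cohort. Missing optional covariates stay `NA`.
#'
#' @param path CSV file path.
#' @param registry Disease registry; defaults to [disease_registry()].
#' @return A [new_cohort()] object.
#' @seealso [write_cohort()] for the inverse; the two round-trip losslessly.
#' @export
read_cohort <- function(path, registry = disease_registry()) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE,
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(mandatory_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: CSV lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- tibble::as_tibble(raw)
  blank_to_na <- function(x) ifelse(trimws(x) == "" | is.na(x), NA, x)
  records[] <- lapply(records, blank_to_na)

  num_cols <- c("sbp", "dbp", "age", "wealth_tertile", "sleep_hours",
                "height_cm", "weight_kg", "waist_cm")
  for (col in intersect(num_cols, names(records))) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }
  flag_cols <- c("self_reported_hypertension",
                 disease_codes(include_hypertension = FALSE))
  for (col in flag_cols) records[[col]] <- parse_flag(records[[col]])
  chr_cols <- c("sex", names(covariate_levels()), "province")
  for (col in intersect(chr_cols, names(records))) {
    records[[col]] <- tolower(as.character(records[[col]]))
  }

  check <- validate_rows(records)
  if (length(check$bad_rows) > 0) {
    warning(sprintf("rejected %d row(s):\n  %s", length(check$bad_rows),
                    paste(check$problems, collapse = "\n  ")),
            call. = FALSE)
    records <- records[-check$bad_rows, , drop = FALSE]
  }
  new_cohort(records, registry)
}

#' Write a cohort to CSV
#'
#' Serialises a cohort so that [read_cohort()] recovers it field-for-field:
#' booleans as 0/1, missing values as empty cells, columns in schema order.
#'
#' @param cohort A `cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort"))
  out <- cohort$records
  flag_cols <- c("self_reported_hypertension",
                 disease_codes(include_hypertension = FALSE))
  for (col in flag_cols) out[[col]] <- as.integer(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}
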