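#' Built-in hypertension diagnostic criteria
#'
#' Two guideline thresholds ship as built-ins: `chl2018` (140/90 mmHg) and
#' `accaha2017` (130/80 mmHg). A criterion is a name plus inclusive
#' systolic/diastolic thresholds; custom criteria can be constructed with
#' [criterion_spec()].
#'
#' @return Named list of criterion specs, in guideline-year order.
#' @examples
#' hypertension_criteria()
#' @export
hypertension_criteria <- function() {
  list(
    chl2018    = criterion_spec("chl2018", 140, 90),
    accaha2017 = criterion_spec("accaha2017", 130, 80)
  )
}

#' Construct a hypertension criterion
#'
#' @param name Short identifier.
#' @param sbp_threshold Systolic threshold, mmHg (inclusive).
#' @param dbp_threshold Diastolic threshold, mmHg (inclusive); must be
#'   below the systolic threshold.
#' @return A `criterion_spec` list.
#' @export
criterion_spec <- function(name, sbp_threshold, dbp_threshold) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(sbp_threshold), is.numeric(dbp_threshold),
            sbp_threshold > 0, dbp_threshold > 0,
            sbp_threshold > dbp_threshold)
  structure(list(name = name,
                 sbp_threshold = as.numeric(sbp_threshold),
                 dbp_threshold = as.numeric(dbp_threshold)),
            class = "criterion_spec")
}

#' Look up a built-in criterion by name
#' @param name `"chl2018"` or `"accaha2017"`.
#' @return A `criterion_spec`.
#' @export
criterion <- function(name) {
  builtin <- hypertension_criteria()
  if (!name %in% names(builtin)) {
    stop("unknown criterion '", name, "'; built-ins: ",
         paste(names(builtin), collapse = ", "), call. = FALSE)
  }
  builtin[[name]]
}

#' Diagnose hypertension under a criterion
#'
#' Final hypertension status is the logical union of the self-reported
#' physician diagnosis and a measured blood-pressure exceedance: positive
#' iff the self-report flag is set, or systolic pressure >= the criterion's
#' systolic threshold, or diastolic pressure >= its diastolic threshold.
#' Comparisons are inclusive, the usual guideline convention.
#'
#' @param sbp,dbp Measured pressures, mmHg (vectors recycle together).
#' @param self_reported Logical self-report flag(s).
#' @param criterion A `criterion_spec`.
#' @return Logical vector of diagnosed status.
#' @examples
#' cri <- hypertension_criteria()
#' diagnose_hypertension(135, 82, FALSE, cri$chl2018)     # FALSE
#' diagnose_hypertension(135, 82, FALSE, cri$accaha2017)  # TRUE
#' @export
diagnose_hypertension <- function(sbp, dbp, self_reported, criterion) {
  stopifnot(inherits(criterion, "criterion_spec"))
  as.logical(self_reported) |
    sbp >= criterion$sbp_threshold |
    dbp >= criterion$dbp_threshold
}

#' Build the N x 26 binary disease matrix
#'
#' Column 1 (hypertension) is derived per participant with
#' [diagnose_hypertension()] under the supplied criterion; the remaining 25
#' columns copy the questionnaire flags. Columns follow registry order
#' regardless of input column order.
#'
#' @param cohort A `cohort` (non-empty).
#' @param criterion A `criterion_spec`.
#' @return Integer matrix of 0/1 with participant ids as rownames, disease
#'   codes as colnames, and attributes `criterion` and class
#'   `disease_matrix`.
#' @export
build_disease_matrix <- function(cohort, criterion) {
  stopifnot(inherits(cohort, "cohort"))
  if (cohort_size(cohort) == 0L) {
    stop("cannot build a disease matrix from an empty cohort", call. = FALSE)
  }
  rec <- cohort$records
  htn <- diagnose_hypertension(rec$sbp, rec$dbp,
                               rec$self_reported_hypertension, criterion)
  flags <- as.matrix(rec[, disease_codes(include_hypertension = FALSE)])
  m <- cbind(hypertension = as.integer(htn), flags * 1L)
  storage.mode(m) <- "integer"
  rownames(m) <- rec$participant_id
  colnames(m) <- disease_codes()
  structure(m, criterion = criterion,
            class = c("disease_matrix", class(m)))
}

#' BMI class under the Chinese obesity criteria
#'
#' BMI = weight / height^2 (kg/m^2), classified as underweight (< 18),
#' normal (18 to < 24), overweight (24 to < 28), obese (>= 28). The printed
#' band labels "18-23.9" and "24-28" are resolved as half-open intervals so
#' every BMI maps to exactly one class. Missing height or weight yields NA.
#'
#' @param height_cm,weight_kg Positive reals (vectors recycle).
#' @return Character vector in
#'   `c("underweight", "normal", "overweight", "obese")`, NA where inputs
#'   are missing.
#' @export
bmi_class <- function(height_cm, weight_kg) {
  n <- max(length(height_cm), length(weight_kg))
  height_cm <- rep_len(height_cm, n); weight_kg <- rep_len(weight_kg, n)
  bad <- (!is.na(height_cm) & height_cm <= 0) |
    (!is.na(weight_kg) & weight_kg <= 0)
  if (any(bad)) stop("height and weight must be positive", call. = FALSE)
  bmi <- weight_kg / (height_cm / 100)^2
  out <- rep(NA_character_, n)
  ok <- !is.na(bmi)
  out[ok] <- as.character(cut(bmi[ok], c(0, 18, 24, 28, Inf),
                              labels = c("underweight", "normal",
                                         "overweight", "obese"),
                              right = FALSE))
  out
}

#' Central obesity by sex-specific waist circumference cutoffs
#'
#' Waist >= 85 cm for men, >= 80 cm for women (inclusive).
#'
#' @param waist_cm Waist circumference, cm (NA allowed).
#' @param sex `"male"` or `"female"`.
#' @return Character vector in `c("normal", "central_obesity")`, NA where
#'   waist is missing.
#' @export
central_obesity <- function(waist_cm, sex) {
  n <- max(length(waist_cm), length(sex))
  waist_cm <- rep_len(waist_cm, n); sex <- rep_len(sex, n)
  if (any(!sex %in% covariate_levels()$sex)) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  if (any(!is.na(waist_cm) & waist_cm <= 0)) {
    stop("waist circumference must be positive", call. = FALSE)
  }
  cut_cm <- ifelse(sex == "male", 85, 80)
  ifelse(is.na(waist_cm), NA_character_,
         ifelse(waist_cm >= cut_cm, "central_obesity", "normal"))
}

#' Band a continuous covariate
#'
#' Named banding schemes used by the tabulations:
#' * `age_table1`: `<45`, `45-64`, `>=65` (edges 45 and 65, left-closed)
#' * `age_subgroup`: `<60`, `>=60`
#' * `sleep`: `<7h`, `7-8h`, `>8h` (7 and 8 inclusive in the middle band)
#'
#' @param value Numeric vector.
#' @param scheme Scheme name.
#' @return Character vector of band labels, NA where `value` is NA.
#' @examples
#' band(c(44, 45, 65), "age_table1")
#' band(7, "sleep")
#' @export
band <- function(value, scheme) {
  out <- switch(scheme,
    age_table1 = cut(value, c(-Inf, 45, 65, Inf),
                     labels = c("<45", "45-64", ">=65"), right = FALSE),
    age_subgroup = cut(value, c(-Inf, 60, Inf),
                       labels = c("<60", ">=60"), right = FALSE),
    sleep = cut(value, c(-Inf, 7, 8, Inf),
                labels = c("<7h", "7-8h", ">8h"),
                right = TRUE, include.lowest = TRUE),
    stop("unknown banding scheme '", scheme, "'", call. = FALSE)
  )
  # sleep: lower edge of the middle band is inclusive ([7, 8]),
  # so reassign exact 7s from "<7h"
  if (scheme == "sleep") {
    out[!is.na(value) & value == 7] <- "7-8h"
  }
  as.character(out)
}
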