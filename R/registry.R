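#' The 26-condition disease registry
#'
#' The fixed, ordered list of chronic conditions analysed by the pipeline:
#' hypertension (derived from measured blood pressure plus self-report)
#' followed by 25 self-reported physician-diagnosed conditions. The registry
#' order defines the column order of every disease matrix, association
#' matrix and dendrogram leaf set produced downstream, so results are
#' invariant to the column order of input files.
#'
#' @return A tibble with columns `code` (snake_case identifier) and `label`
#'   (human-readable condition name), exactly 26 rows, hypertension first.
#' @examples
#' disease_registry()
#' @export
disease_registry <- function() {
  tibble::tibble(
    code = c(
      "hypertension", "diabetes", "ami", "angina", "other_ihd", "stroke_tia",
      "pulm_heart", "rheum_heart", "tuberculosis", "emphysema",
      "chronic_bronchitis", "copd", "asthma", "hepatitis_cirrhosis",
      "peptic_ulcer", "gallstones", "ckd", "osteoporosis", "fracture",
      "rheumatoid_arthritis", "depression", "anxiety", "neurasthenia",
      "other_mental", "brain_injury", "cancer"
    ),
    label = c(
      "Hypertension", "Diabetes", "Acute myocardial infarction", "Angina",
      "Other ischemic heart diseases", "Stroke or TIA",
      "Pulmonary heart disease", "Rheumatic heart disease",
      "Pulmonary tuberculosis", "Emphysema", "Chronic bronchitis", "COPD",
      "Asthma", "Chronic hepatitis or cirrhosis", "Peptic ulcer",
      "Gallstones or cholecystitis", "Chronic kidney disease",
      "Osteoporosis", "Fracture", "Rheumatoid arthritis", "Depression",
      "Anxiety", "Neurasthenia", "Other mental health disorders",
      "Traumatic brain injury", "Cancer"
    )
  )
}

#' Disease codes in registry order
#'
#' @param include_hypertension Keep the derived hypertension condition
#'   (first entry)? The 25 self-reported flags exclude it.
#' @return Character vector of condition codes.
#' @export
disease_codes <- function(include_hypertension = TRUE) {
  codes <- disease_registry()$code
  if (include_hypertension) codes else codes[-1L]
}

assert_known_codes <- function(codes, context = "disease code") {
  bad <- setdiff(codes, disease_codes())
  if (length(bad) > 0) {
    stop(sprintf("unknown %s(s): %s", context, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(codes)
}
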