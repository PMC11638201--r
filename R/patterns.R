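#' Define a multimorbidity pattern
#'
#' @param name Pattern name.
#' @param members At least two registry disease codes.
#' @return A `pattern_definition` list.
#' @export
pattern_definition <- function(name, members) {
  assert_known_codes(members, "pattern member")
  if (length(members) < 2L) {
    stop("a pattern needs at least two member diseases", call. = FALSE)
  }
  structure(list(name = name, members = unique(members)),
            class = "pattern_definition")
}

#' The cardiometabolic pattern
#'
#' Hypertension, diabetes, acute myocardial infarction, angina and
#' stroke/TIA — the five conditions that consistently cluster together.
#'
#' @return A `pattern_definition`.
#' @export
cardiometabolic_pattern <- function() {
  pattern_definition("cardiometabolic", default_pattern_seeds()$cardiometabolic)
}

#' Pattern multimorbidity flags
#'
#' A participant carries pattern multimorbidity when at least two of the
#' pattern's member conditions are present.
#'
#' @param matrix A `disease_matrix`.
#' @param pattern A `pattern_definition`.
#' @return Integer 0/1 vector named by participant id.
#' @export
pattern_flags <- function(matrix, pattern) {
  stopifnot(inherits(matrix, "disease_matrix"),
            inherits(pattern, "pattern_definition"))
  sub <- matrix[, pattern$members, drop = FALSE]
  stats::setNames(as.integer(rowSums(sub) >= 2L), rownames(matrix))
}

#' Component-disease shares within a pattern
#'
#' Among participants with pattern multimorbidity, the count and share of
#' each member disease other than `exclude` (conventionally hypertension,
#' so the shares describe which conditions accompany it).
#'
#' @param matrix A `disease_matrix`.
#' @param pattern A `pattern_definition`.
#' @param exclude Member code to leave out of the breakdown.
#' @return Tibble with columns `code`, `n`, `pct` (share of pattern-flagged
#'   participants, 1 decimal), ordered by registry.
#' @export
component_disease_shares <- function(matrix, pattern,
                                     exclude = "hypertension") {
  stopifnot(inherits(pattern, "pattern_definition"))
  if (!exclude %in% pattern$members) {
    stop("'", exclude, "' is not a member of pattern '", pattern$name, "'",
         call. = FALSE)
  }
  flags <- pattern_flags(matrix, pattern)
  n_flagged <- sum(flags)
  if (n_flagged == 0L) {
    stop("no participant carries pattern multimorbidity; shares undefined",
         call. = FALSE)
  }
  others <- setdiff(pattern$members, exclude)
  counts <- unname(colSums(matrix[flags == 1L, others, drop = FALSE]))
  tibble::tibble(code = others, n = as.integer(counts),
                 pct = pct_of(counts, n_flagged))
}

#' Combination frequencies within a pattern
#'
#' Tabulates disease combinations among the pattern members. Under the
#' default `"exact"` convention a participant is counted once, under the
#' precise member subset they carry; under `"at_least"` a participant
#' contributes to every subset of their member profile (superset-inclusive
#' sensitivity convention). Percentages are of the full cohort, rounded to
#' 2 decimals.
#'
#' @param matrix A `disease_matrix`.
#' @param pattern A `pattern_definition`.
#' @param max_size Largest combination size to report (default all
#'   members).
#' @param convention `"exact"` or `"at_least"`.
#' @return Tibble with columns `combination` (codes joined by `+`), `size`,
#'   `n`, `pct`, sorted by decreasing `n`; combinations with zero carriers
#'   are omitted.
#' @export
combination_frequencies <- function(matrix, pattern,
                                    max_size = length(pattern$members),
                                    convention = c("exact", "at_least")) {
  stopifnot(inherits(matrix, "disease_matrix"),
            inherits(pattern, "pattern_definition"))
  convention <- match.arg(convention)
  members <- pattern$members
  if (max_size < 2 || max_size > length(members)) {
    stop("max_size must be between 2 and the number of pattern members",
         call. = FALSE)
  }
  sub <- matrix[, members, drop = FALSE]
  n_cohort <- nrow(sub)
  profile <- apply(sub == 1L, 1L, function(r) paste(members[r],
                                                    collapse = "+"))
  rows <- list()
  for (size in 2:max_size) {
    combos <- utils::combn(members, size, simplify = FALSE)
    for (combo in combos) {
      key <- paste(combo, collapse = "+")
      n <- if (convention == "exact") {
        sum(profile == key)
      } else {
        sum(rowSums(sub[, combo, drop = FALSE]) == size)
      }
      if (n > 0) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          combination = key, size = size, n = as.integer(n),
          pct = pct_of(n, n_cohort, digits = 2))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(combination = character(0), size = integer(0),
                          n = integer(0), pct = numeric(0)))
  }
  out <- dplyr::bind_rows(rows)
  dplyr::arrange(out, dplyr::desc(.data$n), .data$combination)
}

#' Pattern share among carriers of each disease
#'
#' For every registered condition: among participants who have it, the
#' percentage who carry pattern multimorbidity. A disease with zero
#' carriers yields `NA` with a message.
#'
#' @param matrix A `disease_matrix`.
#' @param pattern A `pattern_definition`.
#' @return Tibble with columns `code`, `n_carriers`, `n_pattern`, `pct`
#'   (1 decimal), in registry order.
#' @export
pattern_share_by_disease <- function(matrix, pattern) {
  flags <- pattern_flags(matrix, pattern)
  codes <- colnames(matrix)
  n_carriers <- unname(colSums(matrix))
  n_pattern <- unname(colSums(matrix * flags))
  pct <- ifelse(n_carriers > 0, pct_of(n_pattern, pmax(n_carriers, 1L)),
                NA_real_)
  if (any(n_carriers == 0)) {
    message("pattern_share_by_disease: no carriers for ",
            paste(codes[n_carriers == 0], collapse = ", "),
            "; share reported as NA")
  }
  tibble::tibble(code = codes, n_carriers = as.integer(n_carriers),
                 n_pattern = as.integer(n_pattern), pct = pct)
}
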