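#' Split a cohort into strata
#'
#' Partitions the cohort by a covariate (optionally banded first, e.g.
#' `by = "age"`, `scheme = "age_subgroup"` for the <60 / >=60 split).
#' Participants with a missing stratifier are dropped with a message.
#' Ethnicity stratification keeps only the five named groups (han, uygur,
#' kazak, hui, tibetan); the residual "other" category is dropped.
#'
#' @param cohort A `cohort`.
#' @param by Covariate name (record column or derived covariate).
#' @param scheme Optional banding scheme passed to [band()].
#' @return Named list of disjoint sub-cohorts.
#' @export
stratify_cohort <- function(cohort, by, scheme = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  values <- if (is.null(scheme)) covariate_values(cohort, by) else
    band(cohort$records[[by]], scheme)
  if (by == "ethnicity") {
    named <- c("han", "uygur", "kazak", "hui", "tibetan")
    values[!values %in% named] <- NA
  }
  n_missing <- sum(is.na(values))
  if (n_missing > 0) {
    message(sprintf("stratify_cohort: dropped %d participant(s) with ",
                    n_missing), "missing '", by, "'")
  }
  keep <- !is.na(values)
  levels <- sort(unique(values[keep]))
  out <- lapply(levels, function(lv) {
    new_cohort(cohort$records[keep & values == lv, , drop = FALSE],
               cohort$registry)
  })
  stats::setNames(out, levels)
}

# one clustering run: disease matrix -> Q -> 1-Q -> Ward -> k-cut,
# dropping constant disease columns for the stratum (Q uninformative)
cluster_stratum <- function(cohort, criterion, k,
                            square_dissimilarity = FALSE) {
  m <- build_disease_matrix(cohort, criterion)
  hits <- colSums(m)
  constant <- colnames(m)[hits == 0L | hits == nrow(m)]
  if (length(constant) > 0) {
    warning("dropping constant disease column(s) for this stratum: ",
            paste(constant, collapse = ", "), call. = FALSE)
    keep <- setdiff(colnames(m), constant)
    m2 <- structure(unclass(m)[, keep, drop = FALSE],
                    criterion = attr(m, "criterion"),
                    class = class(m))
  } else {
    m2 <- m
  }
  if (ncol(m2) < 2L) stop("fewer than two informative diseases in stratum",
                          call. = FALSE)
  assoc <- association_matrix(m2)
  dend <- agglomerate_ward(to_dissimilarity(assoc),
                           square_dissimilarity = square_dissimilarity)
  assignment <- cut_dendrogram(dend, min(k, ncol(m2)))
  list(matrix = m, dendrogram = dend, assignment = assignment,
       excluded = constant)
}

#' Replicate the clustering stack across strata and criteria
#'
#' Re-runs association + Ward clustering within each stratum of a
#' covariate, under each hypertension criterion, and summarises pattern
#' stability as the adjusted Rand index between the per-criterion
#' assignments within each stratum (computed over the diseases retained
#' under both criteria). Strata below `min_n` participants are skipped
#' with a warning; within a stratum, diseases with constant columns are
#' dropped from that stratum's clustering (their pairwise Q is undefined
#' or uninformative) and listed in the result.
#'
#' @param cohort A `cohort`.
#' @param criteria List of `criterion_spec`s (default both built-ins).
#' @param by Stratifying covariate; `NULL` clusters the whole cohort as a
#'   single stratum named `"all"`.
#' @param scheme Optional banding scheme for `by`.
#' @param k Number of clusters to cut (default 4).
#' @param min_n Minimum stratum size (default 100).
#' @param square_dissimilarity Ward dialect switch, see
#'   [agglomerate_ward()].
#' @return List with `results` (`results[[stratum]][[criterion]]` =
#'   dendrogram, assignment, excluded codes), `stability` (tibble: stratum,
#'   criterion pair, n participants, n shared diseases, ARI) and `skipped`
#'   (named sizes of skipped strata).
#' @export
replicate_clustering <- function(cohort,
                                 criteria = hypertension_criteria(),
                                 by = NULL, scheme = NULL, k = 4,
                                 min_n = 100,
                                 square_dissimilarity = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  strata <- if (is.null(by)) list(all = cohort) else
    stratify_cohort(cohort, by, scheme)
  crit_names <- vapply(criteria, `[[`, "", "name")
  names(criteria) <- crit_names

  results <- list(); stab_rows <- list(); skipped <- integer(0)
  for (stratum in names(strata)) {
    sub <- strata[[stratum]]
    if (cohort_size(sub) < min_n) {
      warning(sprintf("stratum '%s' skipped: %d participants < min_n = %d",
                      stratum, cohort_size(sub), min_n), call. = FALSE)
      skipped[stratum] <- cohort_size(sub)
      next
    }
    cell <- lapply(criteria, function(cri) {
      cluster_stratum(sub, cri, k, square_dissimilarity)
    })
    results[[stratum]] <- cell
    if (length(criteria) >= 2) {
      combos <- utils::combn(crit_names, 2, simplify = FALSE)
      for (pair in combos) {
        a1 <- cell[[pair[1]]]$assignment
        a2 <- cell[[pair[2]]]$assignment
        shared <- intersect(names(a1), names(a2))
        stab_rows[[length(stab_rows) + 1L]] <- tibble::tibble(
          stratum = stratum, criterion_a = pair[1], criterion_b = pair[2],
          n = cohort_size(sub), n_diseases = length(shared),
          ari = mclust::adjustedRandIndex(a1[shared], a2[shared]))
      }
    }
  }
  stability <- if (length(stab_rows) > 0) dplyr::bind_rows(stab_rows) else
    tibble::tibble(stratum = character(0), criterion_a = character(0),
                   criterion_b = character(0), n = integer(0),
                   n_diseases = integer(0), ari = numeric(0))
  list(results = results, stability = stability, skipped = skipped)
}
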