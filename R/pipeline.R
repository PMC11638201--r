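#' Run the full multimorbidity analysis pipeline
#'
#' Config-driven end-to-end run: load (or simulate) a cohort, then per
#' hypertension criterion emit the disease-matrix summary, stratified
#' prevalence table, association and dissimilarity matrices, dendrogram
#' (Newick + merge table), k-cut assignment, pattern prevalence table,
#' combination table and per-disease pattern shares; then the stratified
#' replications and a run manifest (config hash, seed, package version,
#' file checksums). Outputs are deterministic: the same config yields
#' byte-identical files.
#'
#' @param config A list, or path to a YAML file, with keys:
#'   \describe{
#'     \item{cohort_csv}{path to an input cohort CSV, or}
#'     \item{synthetic}{list of [synthetic_config()] arguments;}
#'     \item{criteria}{built-in criterion names (default both);}
#'     \item{k}{number of clusters (default 4);}
#'     \item{pattern}{named list `name`, `members` (default the
#'       cardiometabolic pattern);}
#'     \item{strata}{list of `list(by=, scheme=)` stratifiers (default
#'       sex, age <60/>=60, ethnicity);}
#'     \item{min_stratum_n}{minimum stratum size (default 100);}
#'     \item{square_dissimilarity}{Ward dialect switch (default FALSE).}
#'   }
#' @param out_dir Output directory (created; must not contain a previous
#'   run's manifest).
#' @return Path to `out_dir`, invisibly; side effect: files written.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- if (!is.null(cfg$cohort_csv)) read_cohort(cfg$cohort_csv) else
    generate_cohort(do.call(synthetic_config, cfg$synthetic))
  pattern <- pattern_definition(cfg$pattern$name, cfg$pattern$members)
  criteria <- lapply(cfg$criteria, criterion)

  for (cri in criteria) {
    cdir <- file.path(out_dir, cri$name)
    dir.create(cdir, showWarnings = FALSE)
    m <- build_disease_matrix(cohort, cri)
    utils::write.csv(
      data.frame(code = colnames(m), n = colSums(m),
                 pct = pct_of(colSums(m), nrow(m))),
      file.path(cdir, "disease_counts.csv"), row.names = FALSE)

    mm <- multimorbid_flags(m)
    prev <- prevalence_table(
      mm, cohort,
      covariates = c("sex", "age_band", "province", "urbanicity",
                     "ethnicity", "education", "occupation", "marital",
                     "wealth_tertile", "smoking", "drinking", "pa_tertile",
                     "sleep_band", "bmi_class", "central_obesity"))
    utils::write.csv(prev, file.path(cdir, "multimorbidity_prevalence.csv"),
                     row.names = FALSE)

    assoc <- association_matrix(m)
    utils::write.csv(round(unclass(assoc), 6),
                     file.path(cdir, "association_q.csv"))
    dis <- to_dissimilarity(assoc)
    utils::write.csv(round(unclass(dis), 6),
                     file.path(cdir, "dissimilarity.csv"))
    dend <- agglomerate_ward(dis,
                             square_dissimilarity = cfg$square_dissimilarity)
    writeLines(export_newick(dend), file.path(cdir, "dendrogram.nwk"))
    utils::write.csv(merge_table(dend), file.path(cdir, "merges.csv"),
                     row.names = FALSE)
    assignment <- cut_dendrogram(dend, cfg$k)
    cluster_names <- name_clusters(assignment)
    utils::write.csv(
      data.frame(code = names(assignment),
                 cluster = as.integer(assignment),
                 pattern = cluster_names[as.integer(assignment)]),
      file.path(cdir, "assignment.csv"), row.names = FALSE)

    pf <- pattern_flags(m, pattern)
    pprev <- prevalence_table(
      pf, cohort,
      covariates = c("sex", "age_band", "bmi_class", "central_obesity"),
      outcome_name = paste0(pattern$name, "_multimorbidity"))
    utils::write.csv(pprev, file.path(cdir, "pattern_prevalence.csv"),
                     row.names = FALSE)
    utils::write.csv(combination_frequencies(m, pattern),
                     file.path(cdir, "combinations.csv"), row.names = FALSE)
    utils::write.csv(component_disease_shares(m, pattern),
                     file.path(cdir, "component_shares.csv"),
                     row.names = FALSE)
    utils::write.csv(pattern_share_by_disease(m, pattern),
                     file.path(cdir, "pattern_share_by_disease.csv"),
                     row.names = FALSE)
  }

  # stratified replications + stability summary
  stab <- list()
  for (st in cfg$strata) {
    rep <- replicate_clustering(cohort, criteria, by = st$by,
                                scheme = st$scheme, k = cfg$k,
                                min_n = cfg$min_stratum_n,
                                square_dissimilarity =
                                  cfg$square_dissimilarity)
    for (stratum in names(rep$results)) {
      for (cri_name in names(rep$results[[stratum]])) {
        sdir <- file.path(out_dir, "strata", st$by,
                          paste0(stratum, "_", cri_name))
        dir.create(sdir, recursive = TRUE, showWarnings = FALSE)
        cell <- rep$results[[stratum]][[cri_name]]
        writeLines(export_newick(cell$dendrogram),
                   file.path(sdir, "dendrogram.nwk"))
        utils::write.csv(merge_table(cell$dendrogram),
                         file.path(sdir, "merges.csv"), row.names = FALSE)
        utils::write.csv(
          data.frame(code = names(cell$assignment),
                     cluster = as.integer(cell$assignment)),
          file.path(sdir, "assignment.csv"), row.names = FALSE)
        if (length(cell$excluded) > 0) {
          writeLines(cell$excluded, file.path(sdir, "excluded_diseases.txt"))
        }
      }
    }
    if (nrow(rep$stability) > 0) {
      rep$stability$stratifier <- st$by
      stab[[length(stab) + 1L]] <- rep$stability
    }
  }
  if (length(stab) > 0) {
    utils::write.csv(dplyr::bind_rows(stab),
                     file.path(out_dir, "stability_summary.csv"),
                     row.names = FALSE)
  }

  files <- sort(list.files(out_dir, recursive = TRUE, full.names = TRUE))
  manifest <- list(
    config = cfg,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("morbclust")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    files = stats::setNames(as.character(tools::md5sum(files)),
                            sub(paste0(out_dir, "/?"), "", files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

validate_pipeline_config <- function(config) {
  stopifnot(is.list(config))
  problems <- character(0)
  if (is.null(config$cohort_csv) && is.null(config$synthetic)) {
    problems <- c(problems, "config needs 'cohort_csv' or 'synthetic'")
  }
  if (!is.null(config$cohort_csv) && !is.null(config$synthetic)) {
    problems <- c(problems,
                  "'cohort_csv' and 'synthetic' are mutually exclusive")
  }
  cfg <- list(
    cohort_csv = config$cohort_csv,
    synthetic = config$synthetic,
    criteria = config$criteria %||% c("chl2018", "accaha2017"),
    k = config$k %||% 4L,
    pattern = config$pattern %||%
      list(name = "cardiometabolic",
           members = default_pattern_seeds()$cardiometabolic),
    strata = config$strata %||%
      list(list(by = "sex", scheme = NULL),
           list(by = "age", scheme = "age_subgroup"),
           list(by = "ethnicity", scheme = NULL)),
    min_stratum_n = config$min_stratum_n %||% 100L,
    square_dissimilarity = isTRUE(config$square_dissimilarity))
  bad_crit <- setdiff(cfg$criteria, names(hypertension_criteria()))
  if (length(bad_crit) > 0) {
    problems <- c(problems, paste0("unknown criterion: ",
                                   paste(bad_crit, collapse = ", ")))
  }
  bad_members <- setdiff(cfg$pattern$members, disease_codes())
  if (length(bad_members) > 0) {
    problems <- c(problems, paste0("unknown pattern member: ",
                                   paste(bad_members, collapse = ", ")))
  }
  if (cfg$k < 1 || cfg$k > 26) problems <- c(problems, "k out of range")
  if (length(problems) > 0) {
    stop("invalid pipeline config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  cfg
}
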