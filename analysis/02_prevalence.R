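#!/usr/bin/env Rscript
# Multimorbidity prevalence under the two hypertension criteria:
# characteristics-table-style stratified prevalence for each, plus the
# condition-count distribution. Expects results/cohort.csv from step 01.

library(morbclust)

cohort <- read_cohort("results/cohort.csv")
covs <- c("sex", "age_band", "province", "urbanicity", "ethnicity",
          "education", "occupation", "marital", "wealth_tertile",
          "smoking", "drinking", "pa_tertile", "sleep_band", "bmi_class",
          "central_obesity")

for (cri in hypertension_criteria()) {
  m <- build_disease_matrix(cohort, cri)
  flags <- multimorbid_flags(m)
  tab <- prevalence_table(flags, cohort, covariates = covs)
  write.csv(tab, sprintf("results/02_prevalence_%s.csv", cri$name),
            row.names = FALSE)
  write.csv(condition_count_distribution(m),
            sprintf("results/02_condition_counts_%s.csv", cri$name),
            row.names = FALSE)
  cat(sprintf("%s (%d/%d mmHg): hypertension %.1f%%, multimorbidity %.1f%%\n",
              cri$name, cri$sbp_threshold, cri$dbp_threshold,
              100 * mean(m[, "hypertension"]), 100 * mean(flags)))
}
cat("stratified tables -> results/02_prevalence_*.csv\n")
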