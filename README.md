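# morbclust

Multimorbidity pattern discovery for chronic-disease survey cohorts, built
around one question: **does tightening the hypertension diagnostic
threshold from 140/90 to 130/80 mmHg change how chronic diseases cluster
into multimorbidity patterns, or only how many people carry them?**

The package is aimed at epidemiologists analysing cross-sectional survey
data in which one condition (hypertension) is diagnosed from measured
blood pressure plus self-report under a configurable guideline criterion,
while the remaining conditions are self-reported physician diagnoses.

## The method

For a cohort of N participants and a fixed registry of 26 chronic
conditions (hypertension first):

1. **Diagnosis.** Hypertension is positive iff
   `self_report ∨ SBP ≥ s ∨ DBP ≥ d` for an inclusive criterion (s, d);
   the built-ins are 140/90 (`chl2018`) and 130/80 (`accaha2017`) mmHg.
   The other 25 flags are taken from the questionnaire, giving an N × 26
   binary disease matrix per criterion. Multimorbidity = ≥ 2 conditions.
2. **Association.** For each disease pair, the 2 × 2 table (a, b, c, d)
   yields Yule's Q = (ad − bc)/(ad + bc) ∈ [−1, 1]; degenerate tables
   (ad + bc = 0) receive a logged +0.5 continuity correction.
3. **Clustering.** Diseases are clustered agglomeratively on the
   dissimilarity 1 − Q with Ward's method, implemented via the
   Lance–Williams recurrence
   `D(ij,k) = [(nᵢ+nₖ)D(i,k) + (nⱼ+nₖ)D(j,k) − nₖD(i,j)] / (nᵢ+nⱼ+nₖ)`
   applied to the dissimilarities as supplied (`ward.D` dialect; a
   `square_dissimilarity` switch gives the `ward.D2` dialect). The
   dendrogram is cut at k = 4 and clusters are named against seed lists
   (cardiometabolic, respiratory, digestive-bone-kidney, mental-cancer).
4. **Pattern analytics.** Cardiometabolic multimorbidity (≥ 2 of
   hypertension, diabetes, AMI, angina, stroke/TIA), exact combination
   frequencies on the full-cohort base, component-disease shares among the
   pattern-multimorbid, and the pattern's share among carriers of each
   disease — all replicated under both criteria and within sex / age /
   ethnicity strata, with cross-criterion agreement summarised by the
   adjusted Rand index.

Because raw survey data of this kind are rarely shareable, the package
ships a latent-threshold synthetic cohort generator
(`synthetic_config()` / `generate_cohort()`) that plants a known 4-block
association structure, marginal prevalences in the few-percent range, and
a blood-pressure distribution with mass in the 130–139/80–89 band, so the
whole pipeline can be validated against ground truth.

## Worked example

```r
library(morbclust)

cfg    <- synthetic_config(n = 20000, seed = 42)   # default study conditions
cohort <- generate_cohort(cfg)
cri    <- hypertension_criteria()

m_std <- build_disease_matrix(cohort, cri$chl2018)     # 140/90
m_int <- build_disease_matrix(cohort, cri$accaha2017)  # 130/80
c(mean(multimorbid_flags(m_std)), mean(multimorbid_flags(m_int)))
#> [1] 0.1654 0.2191

asg <- cut_dendrogram(
  agglomerate_ward(to_dissimilarity(association_matrix(m_std))), k = 4)
split(names(asg), name_clusters(asg)[as.integer(asg)])$cardiometabolic
#> [1] "hypertension" "diabetes"     "ami"          "angina"       "stroke_tia"

asg_int <- cut_dendrogram(
  agglomerate_ward(to_dissimilarity(association_matrix(m_int))), k = 4)
mclust::adjustedRandIndex(asg, asg_int)
#> [1] 1
```

Reading: under the intensive criterion multimorbidity prevalence rises
from 16.5% to 21.9% of the cohort, yet the k = 4 cluster assignment is
identical (ARI = 1) — the criterion revision grows the patient population
without rearranging the disease patterns, and hypertension stays inside
the cardiometabolic cluster.

## Analysis workflow

The `analysis/` directory holds the narrative pipeline, each step a thin
driver over the package that prints what it found and writes tables under
`results/`:

| script | step |
|---|---|
| `01_simulate.R` | simulate the default cohort, check marginals |
| `02_prevalence.R` | stratified multimorbidity prevalence, both criteria |
| `03_cluster_patterns.R` | Yule's Q → Ward dendrograms → named k = 4 patterns |
| `04_cardiometabolic.R` | pattern prevalence, combinations, component shares |
| `05_subgroups.R` | sex / age / ethnicity replication + stability summary |

Run them in order from the repository root (`Rscript analysis/01_simulate.R`, …).
`run_pipeline()` performs the same end-to-end analysis from a single YAML
config (see `inst/extdata/pipeline_config_example.yaml`) and writes a
manifest of file checksums for reproducibility.

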