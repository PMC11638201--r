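---
title: "Multimorbidity patterns under alternative hypertension criteria: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimorbidity patterns under alternative hypertension criteria: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morbclust)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations.

## The analysis model

The pipeline takes one-row-per-participant survey records for a fixed,
ordered registry of 26 chronic conditions. Hypertension is special: its
final status is *derived* as the logical union of a self-reported
physician diagnosis and a measured blood-pressure exceedance under a named
criterion, so the same cohort yields one disease matrix per criterion.
The two built-in criteria are 140/90 mmHg (`chl2018`) and 130/80 mmHg
(`accaha2017`); comparisons are inclusive (≥), the usual guideline
convention, since equality at the threshold is a diagnosis in both
guidelines. The union reading of "measurement plus self-report" is the
standard epidemiological ascertainment for survey data, where treated
hypertensives may present controlled pressures; a treatment-based
definition is out of scope because medication use is not in the data
model.

The remaining 25 conditions are questionnaire flags taken at face value.
Multimorbidity is ≥ 2 conditions out of the 26. Because the intensive
criterion can only add hypertension diagnoses, hypertension,
multimorbidity and pattern flags under 130/80 dominate those under 140/90
element-wise — a monotonicity invariant the test suite checks on every
synthetic cohort.

## Association: Yule's Q

Pairwise disease association uses Yule's Q = (ad − bc)/(ad + bc) on the
2 × 2 joint table. Q is marginal-free in the sense that it depends only on
the odds ratio, which makes it usable across conditions whose prevalences
differ by an order of magnitude — the reason it is preferred over phi-type
coefficients for rare chronic diseases.

Degenerate tables need a rule. When ad + bc = 0 (which covers every
zero-marginal table), Q is undefined; the package applies the
Haldane–Anscombe continuity correction (+0.5 to all four cells) *for that
pair only*, emits a message, and records the event. A single vanishing
cross product (only b = 0 or only c = 0) is left uncorrected: Q = ±1 is
then the exact, informative answer. Constant columns — a disease everyone
or no one carries — are rejected by `association_matrix()` with an error
naming the disease, because every Q involving it is uninformative;
`replicate_clustering()` instead drops such columns per stratum with a
warning — our own convention for sparse strata, stated here because there
is no field-standard rule to defer to.

## Clustering: Ward on 1 − Q

The dissimilarity is d = 1 − Q (range [0, 2]). Ward agglomeration is
implemented directly via the Lance–Williams recurrence with coefficients
αᵢ = (nᵢ+nₖ)/(nᵢ+nⱼ+nₖ), αⱼ = (nⱼ+nₖ)/(nᵢ+nⱼ+nₖ), β = −nₖ/(nᵢ+nⱼ+nₖ),
γ = 0.

Two genuinely open design points and how we resolved them:

* **Dialect.** Applying the recurrence to d as supplied is the `ward.D`
  convention; applying it to d² and reporting square-rooted heights is
  `ward.D2`. Since 1 − Q is not a squared Euclidean distance, neither is
  canonical. The default is `ward.D` (the long-standing behaviour of the
  R clustering ecosystem this analysis style comes from), and
  `square_dissimilarity = TRUE` switches dialects. On the default
  synthetic cohort both dialects produce the same k = 4 partition.
* **Tie-breaking.** Among equal minimal distances the pair with the
  lexicographically smallest (cluster-index, cluster-index) in the current
  active-cluster order is merged, which makes the merge sequence — and
  hence every downstream artifact — deterministic. Continuous inputs make
  ties measure-zero, but binary data can produce exactly tied Q values.

Ward linkage is reducible, so merge heights are non-decreasing; the
implementation is verified in the tests against (i) a naive O(n³) re-scan
oracle that recomputes every cluster distance from the original matrix
with the closed-form Ward/ESS expression, never using the incremental
update, and (ii) `stats::hclust` for both dialects.

The number of clusters k is a parameter, default 4: the pipeline treats k
as given and reports merge heights (`merge_table()`) to support visual
inspection rather than selecting k by an internal criterion. Cutting
undoes the last k − 1 merges; cluster ids are numbered by first appearance
in registry order, and `name_clusters()` attaches pattern names by maximal
overlap with configurable seed lists rather than by cluster position.

## Pattern analytics

The cardiometabolic pattern is {hypertension, diabetes, AMI, angina,
stroke/TIA}; pattern multimorbidity is ≥ 2 of its members. Combination
frequencies default to the **exact-profile** convention — each participant
counts once, under precisely the member subset they carry — because
published full-pattern counts ("all five diseases") read as exact
profiles; a superset-inclusive `at_least` convention is available as a
sensitivity switch. Combination percentages use the full cohort as base
(2 decimals); stratified prevalence percentages are per level (1 decimal).
All rounding goes through one helper, `round_half_up()`, because
reproducing conventionally rounded survey tables requires half-away-from-
zero rather than banker's rounding; the published count/percentage pairs
we checked all reproduce under this rule.

Participants missing a covariate are excluded from that covariate's
strata only, never from the disease analyses; nothing is imputed.

## The synthetic cohort generator

Real cohorts of this kind are not shareable, so validation runs on
synthetic cohorts with planted structure. The generator uses a Gaussian
latent-threshold (copula-style) construction: each participant draws one
standard-normal factor per block, a block member's liability is
√ρ·factor + √(1−ρ)·noise plus an age gradient (β = 0.3 per SD of age,
standardised so target marginals are preserved), and the flag is the
liability exceeding the normal quantile of the target prevalence. This
was chosen over direct Bernoulli mixtures because it gives smooth,
controllable positive within-block association measurable by Yule's Q —
exactly what the clustering stage assumes.

Default study conditions, fixed once: n = 20,000; four blocks mirroring
the four patterns with ρ = 0.5; two noise diseases (other ischemic heart
diseases, rheumatic heart disease) with no cross-correlation; marginal
prevalences in the 0.6–6% range typical of self-reported chronic disease,
with hypertension far more common by construction. Blood pressure is
bivariate normal (SBP ~ N(126, 16), DBP ~ N(76, 10), residual correlation
0.6) with a loading of 0.6 on the cardiometabolic factor — this both
places hypertension inside its block and populates the 130–139/80–89 band
so that criterion switching reclassifies a substantial group (diagnosed
hypertension ≈ 22% under 140/90 vs ≈ 49% under 130/80, the latter typical
of intensive-criterion estimates in middle-aged and older populations).
Self-reported hypertension is set for 50% of the top-20% liability
stratum, emulating imperfect awareness. Covariates are drawn from
categorical distributions with a rural-majority, multi-ethnic composition.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: no ethnicity- or sex-specific disease
structure (subgroup replications succeed by construction of symmetry), no
survey weights or household clustering, no reporting bias correlated with
education or access, no treatment effects on measured blood pressure, and
exact published prevalences are not reproduced (the source data are
unavailable; no test claims otherwise). Small strata do exhibit honest
estimation noise: in the narrative subgroup run the ~250-participant
stratum shows unstable assignments, mirroring how sparse subgroups resist
pattern identification in practice.

## Problem sizes and numerical choices

Tests and the acceptance script use n = 20,000 cohorts for
distribution-level checks (marginals within ±1 percentage point;
parameter recovery with ARI = 1 in ≥ 95% of 20 replicates under ρ = 0.5)
and n in the hundreds-to-thousands range for recount and invariant
oracles — sizes at which every run completes in seconds while keeping
Yule's Q estimates stable for the prevalence range involved. Recovery
scoring excludes the noise diseases: where they attach to a block is
estimation noise by design, not part of the planted truth. Dissimilarity
symmetry is validated to 1e-8; oracle-equivalence comparisons use 1e-10
relative tolerance on heights and exact equality on merge sequences.

## Known limitations

* Yule's Q on very rare disease pairs is inherently unstable (an empty
  co-occurrence cell pins Q at −1); the independence-limit test
  consequently asserts distributional symmetry and well-powered pairs
  rather than uniform smallness, and real analyses should treat
  associations among sub-1% conditions with the same caution.
* The ward.D/ward.D2 choice can matter for data without clear block
  structure; both are exposed, only one can be the default.
* One blood-pressure reading per participant; repeat-measurement
  averaging belongs upstream.
* Cross-sectional flags only: no onset ordering, no longitudinal
  trajectories, no causal claims.
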