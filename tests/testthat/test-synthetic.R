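test_that("the generator is reproducible and validates its config", {
  cfg <- synthetic_config(n = 400, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$records, b$records)
  c2 <- generate_cohort(synthetic_config(n = 400, seed = 100))
  expect_false(identical(a$records, c2$records))

  expect_error(synthetic_config(n = 0), "positive integer")
  expect_equal(cohort_size(generate_cohort(synthetic_config(n = 1))), 1L)
  expect_error(synthetic_config(marginal_prevalences = c(diabetes = 0.5)),
               "25 questionnaire")
  bad <- default_marginals(); bad["diabetes"] <- 1.5
  expect_error(synthetic_config(marginal_prevalences = bad), "\\(0, 1\\)")
  blocks <- default_blocks(); blocks[[1]]$within_correlation <- 1
  expect_error(synthetic_config(blocks = blocks), "within_correlation")
})

test_that("empirical marginals hit their targets within one percentage point", {
  cfg <- synthetic_config()  # default: n = 20000, seed = 42
  co <- generate_cohort(cfg)
  emp <- colMeans(as.matrix(co$records[, disease_codes(FALSE)]))
  expect_true(all(abs(emp - cfg$marginal_prevalences) < 0.01))
})

test_that("zero within-block correlation leaves all pairs near-independent", {
  blocks <- lapply(default_blocks(), function(b) {
    b$within_correlation <- 0; b
  })
  # age gradient off too: a shared age effect is itself a source of
  # positive pairwise association
  cfg <- synthetic_config(n = 20000, seed = 55, blocks = blocks,
                          bp_model = list(sbp_mean = 126, sbp_sd = 16,
                                          dbp_mean = 76, dbp_sd = 10,
                                          factor_loading = 0,
                                          residual_cor = 0.6),
                          covariate_model = list(age_effect = 0))
  m <- build_disease_matrix(generate_cohort(cfg), criterion("chl2018"))
  q <- unclass(association_matrix(m))
  # Q is only stably estimated where co-occurrence is expected; for two
  # sub-1% diseases an empty a-cell pins Q at -1 by definition, so judge
  # near-independence on pairs with expected co-occurrence >= 5
  p <- colMeans(unclass(m))
  expected_a <- nrow(m) * outer(p, p)
  stable <- upper.tri(q) & expected_a >= 5
  # sampling noise is symmetric about zero under independence
  expect_lt(abs(mean(q[stable])), 0.05)
  expect_lt(stats::median(abs(q[stable])), 0.15)
  # well-powered pairs are individually near zero
  strong <- upper.tri(q) & expected_a >= 50
  expect_true(any(strong))
  expect_lt(max(abs(q[strong])), 0.25)
  # and no planted structure: within-block association does not exceed
  # between-block association on average
  gt <- ground_truth(cfg)
  codes <- names(gt)
  same_block <- outer(gt, gt, `==`)[codes, codes]
  sub <- q[codes, codes]
  ut <- upper.tri(sub)
  expect_lt(abs(mean(sub[ut & same_block]) - mean(sub[ut & !same_block])),
            0.1)
})

test_that("ground truth reflects the blocks, independent of seed", {
  gt42 <- ground_truth(synthetic_config(seed = 42))
  gt7 <- ground_truth(synthetic_config(seed = 7))
  expect_identical(gt42, gt7)
  expect_equal(attr(gt42, "k"), 4L)
  seeds <- default_pattern_seeds()
  for (nm in names(seeds)) {
    ids <- unique(gt42[seeds[[nm]]])
    expect_length(ids, 1L)
  }
  # noise diseases are excluded from the truth
  expect_false(any(c("other_ihd", "rheum_heart") %in% names(gt42)))
  single <- synthetic_config(blocks = list(list(
    name = "only", members = c("diabetes", "copd"),
    within_correlation = 0.4)))
  expect_equal(attr(ground_truth(single), "k"), 1L)
})

test_that("diagnosed hypertension strictly increases under the intensive criterion", {
  for (seed in c(1, 2, 3)) {
    co <- generate_cohort(synthetic_config(n = 5000, seed = seed))
    rec <- co$records
    std <- mean(diagnose_hypertension(rec$sbp, rec$dbp,
                                      rec$self_reported_hypertension,
                                      criterion("chl2018")))
    int <- mean(diagnose_hypertension(rec$sbp, rec$dbp,
                                      rec$self_reported_hypertension,
                                      criterion("accaha2017")))
    expect_gt(int, std)
  }
})

test_that("generated records satisfy the cohort invariants", {
  co <- generate_cohort(synthetic_config(n = 2000, seed = 44))
  rec <- co$records
  expect_true(all(rec$sbp > rec$dbp))
  expect_true(all(rec$dbp > 0))
  expect_true(all(rec$age >= 35 & rec$age <= 74))
  expect_false(anyDuplicated(rec$participant_id) > 0)
  expect_true(all(rec$sex %in% c("male", "female")))
})
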