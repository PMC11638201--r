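cardio <- cardiometabolic_pattern()

test_that("pattern flags need at least two member conditions", {
  # hypertension + diabetes -> flagged; hypertension alone -> not
  both <- as_dm(matrix(c(1L, 1L, rep(0L, 24)), 1))
  expect_equal(unname(pattern_flags(both, cardio)), 1L)
  solo <- as_dm(matrix(c(1L, rep(0L, 25)), 1))
  expect_equal(unname(pattern_flags(solo, cardio)), 0L)
  expect_error(pattern_definition("x", "hypertension"), "at least two")
  expect_error(pattern_definition("x", c("hypertension", "nope")),
               "unknown")
})

test_that("pattern flags equal a brute-force member recount", {
  set.seed(20)
  m <- random_disease_matrix(200)
  flags <- pattern_flags(m, cardio)
  brute <- apply(unclass(m)[, cardio$members], 1,
                 function(r) as.integer(sum(r) >= 2))
  expect_equal(unname(flags), unname(brute))
})

test_that("component shares are counted among pattern-flagged participants", {
  set.seed(22)
  m <- random_disease_matrix(300, p = 0.25)
  shares <- component_disease_shares(m, cardio, exclude = "hypertension")
  flags <- pattern_flags(m, cardio)
  expect_setequal(shares$code, setdiff(cardio$members, "hypertension"))
  for (i in seq_len(nrow(shares))) {
    n <- sum(m[flags == 1L, shares$code[i]])
    expect_equal(shares$n[i], n)
    expect_equal(shares$pct[i], round_half_up(100 * n / sum(flags), 1))
  }
  # everyone flagged has diabetes -> share 100
  forced <- unclass(m)
  forced[flags == 1L, "diabetes"] <- 1L
  shares2 <- component_disease_shares(as_dm(forced), cardio)
  expect_equal(shares2$pct[shares2$code == "diabetes"], 100)
  empty <- as_dm(matrix(0L, 4, 26))
  expect_error(component_disease_shares(empty, cardio), "no participant")
  expect_error(component_disease_shares(m, cardio, exclude = "copd"),
               "not a member")
})

test_that("exact combination counts match brute-force subset enumeration", {
  set.seed(24)
  m <- random_disease_matrix(100, p = 0.3)
  tab <- combination_frequencies(m, cardio)
  sub <- unclass(m)[, cardio$members]
  profiles <- apply(sub, 1, function(r) paste(cardio$members[r == 1],
                                              collapse = "+"))
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$n[i], sum(profiles == tab$combination[i]))
    expect_equal(tab$pct[i], round_half_up(100 * tab$n[i] / 100, 2))
  }
  # exact-profile counts over all subsets partition the flagged participants
  expect_equal(sum(tab$n), sum(pattern_flags(m, cardio)))
  # all-zero matrix -> empty table
  expect_equal(nrow(combination_frequencies(as_dm(matrix(0L, 5, 26)),
                                            cardio)), 0L)
  expect_error(combination_frequencies(m, cardio, max_size = 1), "max_size")
})

test_that("at-least counting is superset-inclusive and dominates exact counts", {
  set.seed(26)
  m <- random_disease_matrix(150, p = 0.3)
  exact <- combination_frequencies(m, cardio, convention = "exact")
  atleast <- combination_frequencies(m, cardio, convention = "at_least")
  sub <- unclass(m)[, cardio$members]
  for (i in seq_len(nrow(atleast))) {
    combo <- strsplit(atleast$combination[i], "+", fixed = TRUE)[[1]]
    expect_equal(atleast$n[i],
                 sum(rowSums(sub[, combo, drop = FALSE]) == length(combo)))
    ex <- exact$n[exact$combination == atleast$combination[i]]
    if (length(ex) == 1) expect_gte(atleast$n[i], ex)
  }
})

test_that("pattern share by disease equals a brute-force recount", {
  set.seed(28)
  m <- random_disease_matrix(250, p = 0.2)
  flags <- pattern_flags(m, cardio)
  tab <- pattern_share_by_disease(m, cardio)
  expect_equal(tab$code, disease_codes())
  for (i in sample(26, 6)) {
    carriers <- m[, i] == 1L
    expect_equal(tab$n_carriers[i], sum(carriers))
    expect_equal(tab$n_pattern[i], sum(flags[carriers]))
    expect_equal(tab$pct[i],
                 round_half_up(100 * sum(flags[carriers]) / sum(carriers), 1))
  }
  # a disease with no carriers reports NA with a message
  none <- unclass(m); none[, "cancer"] <- 0L
  expect_message(tab2 <- pattern_share_by_disease(as_dm(none), cardio),
                 "cancer")
  expect_true(is.na(tab2$pct[tab2$code == "cancer"]))
})

test_that("pattern multimorbidity implies multimorbidity and grows under 130/80", {
  co <- generate_cohort(synthetic_config(n = 3000, seed = 33))
  m_std <- build_disease_matrix(co, criterion("chl2018"))
  m_int <- build_disease_matrix(co, criterion("accaha2017"))
  pf_std <- pattern_flags(m_std, cardio)
  pf_int <- pattern_flags(m_int, cardio)
  expect_true(all(pf_std <= multimorbid_flags(m_std)))
  expect_true(all(pf_int >= pf_std))
})
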