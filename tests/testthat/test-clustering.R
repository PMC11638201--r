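test_that("contingency tables give exact joint counts", {
  m <- as_dm(cbind(c(1, 1, 0, 0), c(1, 0, 1, 0)))
  tab <- contingency(m, "hypertension", "diabetes")
  expect_equal(unclass(tab)[c("a", "b", "c", "d")],
               list(a = 1L, b = 1L, c = 1L, d = 1L))
  same <- as_dm(cbind(c(1, 1, 0), c(1, 1, 0)))
  tab2 <- contingency(same, "hypertension", "diabetes")
  expect_equal(tab2$b + tab2$c, 0L)
  expect_error(contingency(m, "hypertension", "hypertension"), "distinct")
  expect_error(contingency(m, "hypertension", "nope"), "unknown")
})

test_that("contingency matches a brute-force row loop", {
  set.seed(2)
  m <- random_disease_matrix(200, ncol = 4)
  codes <- colnames(m)
  for (pair in list(c(1, 2), c(2, 4), c(1, 3))) {
    tab <- contingency(m, codes[pair[1]], codes[pair[2]])
    x <- m[, pair[1]]; y <- m[, pair[2]]
    brute <- c(a = 0L, b = 0L, c = 0L, d = 0L)
    for (r in seq_len(nrow(m))) {
      cell <- if (x[r] && y[r]) "a" else if (x[r]) "b" else
        if (y[r]) "c" else "d"
      brute[cell] <- brute[cell] + 1L
    }
    expect_equal(unlist(unclass(tab)[c("a", "b", "c", "d")]), brute)
  }
})

test_that("Yule's Q matches the cross-product formula and its symmetries", {
  expect_equal(as.numeric(yule_q(list(a = 25, b = 25, c = 25, d = 25))), 0)
  expect_equal(as.numeric(yule_q(list(a = 7, b = 0, c = 0, d = 13))), 1)
  expect_equal(as.numeric(yule_q(list(a = 30, b = 10, c = 20, d = 40))),
               1000 / 1400)
  expect_error(yule_q(list(a = 0, b = 0, c = 0, d = 0)), "all-zero")
  set.seed(6)
  for (rep in 1:25) {
    t <- as.list(stats::setNames(rpois(4, 20) + 1, c("a", "b", "c", "d")))
    q <- as.numeric(yule_q(t))
    expect_equal(q, (t$a * t$d - t$b * t$c) / (t$a * t$d + t$b * t$c))
    expect_gte(q, -1); expect_lte(q, 1)
    # swapping both margins (a<->d, b<->c) leaves Q unchanged
    expect_equal(as.numeric(yule_q(list(a = t$d, b = t$c, c = t$b,
                                        d = t$a))), q)
    # recoding one disease (a<->b, c<->d) negates Q
    expect_equal(as.numeric(yule_q(list(a = t$b, b = t$a, c = t$d,
                                        d = t$c))), -q)
  }
})

test_that("degenerate tables get a logged continuity correction", {
  expect_message(q <- yule_q(list(a = 5, b = 0, c = 3, d = 0)),
                 "continuity correction")
  expect_true(attr(q, "corrected"))
  expect_gte(as.numeric(q), -1); expect_lte(as.numeric(q), 1)
  # one vanishing cross product alone is exact +/-1, no correction
  q1 <- yule_q(list(a = 9, b = 0, c = 4, d = 8))
  expect_equal(as.numeric(q1), 1)
  expect_false(attr(q1, "corrected"))
  qm1 <- yule_q(list(a = 0, b = 3, c = 5, d = 0))
  expect_equal(as.numeric(qm1), -1)
  expect_false(attr(qm1, "corrected"))
})

test_that("association matrix is symmetric with unit diagonal and matches yule_q", {
  set.seed(10)
  m <- random_disease_matrix(300)
  q <- association_matrix(m)
  expect_equal(unclass(q), t(unclass(q)))
  expect_equal(unname(diag(q)), rep(1, 26))
  codes <- colnames(m)
  for (pair in list(c(1, 2), c(5, 20), c(13, 26))) {
    expect_equal(q[pair[1], pair[2]],
                 as.numeric(yule_q(contingency(m, codes[pair[1]],
                                               codes[pair[2]]))))
  }
})

test_that("association matrix flags duplicated, independent and constant columns", {
  set.seed(12)
  x <- rbinom(10000, 1, 0.3)
  dup <- as_dm(cbind(x, x, rbinom(10000, 1, 0.2)))
  q <- association_matrix(dup)
  expect_equal(q[1, 2], 1)
  indep <- as_dm(cbind(rbinom(10000, 1, 0.3), rbinom(10000, 1, 0.25)))
  expect_lt(abs(association_matrix(indep)[1, 2]), 0.1)
  const <- as_dm(cbind(x, rep(1L, 10000)))
  expect_error(association_matrix(const), "constant.*diabetes")
})

test_that("within-block association exceeds between-block association", {
  co <- generate_cohort(synthetic_config(n = 10000, seed = 31))
  m <- build_disease_matrix(co, criterion("chl2018"))
  q <- association_matrix(m)
  gt <- ground_truth(synthetic_config(n = 10000, seed = 31))
  codes <- names(gt)
  within <- c(); between <- c()
  for (i in codes) for (j in codes) {
    if (i < j) {
      if (gt[i] == gt[j]) within <- c(within, q[i, j]) else
        between <- c(between, q[i, j])
    }
  }
  expect_gt(min(within), max(between))
})

test_that("dissimilarity is 1 - Q off-diagonal with zero diagonal", {
  set.seed(14)
  m <- random_disease_matrix(300)
  q <- association_matrix(m)
  d <- to_dissimilarity(q)
  expect_equal(unname(diag(d)), rep(0, 26))
  off <- upper.tri(d)
  expect_equal(d[off], 1 - unclass(q)[off])
  expect_true(all(d >= 0 & d <= 2))
})

test_that("two leaves merge once at their dissimilarity", {
  d <- matrix(c(0, 0.7, 0.7, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  dend <- agglomerate_ward(d)
  expect_equal(nrow(dend$merge), 1L)
  expect_equal(dend$height, 0.7)
  expect_equal(dend$merge[1, ], c(-2L, -1L))
})

test_that("well-separated pairs are merged first", {
  d <- matrix(1.9, 4, 4); diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.1
  d[3, 4] <- d[4, 3] <- 0.1
  dimnames(d) <- list(LETTERS[1:4], LETTERS[1:4])
  dend <- agglomerate_ward(d)
  expect_equal(dend$merge[1, ], c(-2L, -1L))
  expect_equal(dend$merge[2, ], c(-4L, -3L))
  expect_equal(dend$height[1:2], c(0.1, 0.1))
})

test_that("merge sequence matches the naive O(n^3) re-scan oracle", {
  set.seed(100)
  for (trial in 1:100) {
    n <- sample(3:10, 1)
    d <- random_dissimilarity(n)
    dend <- agglomerate_ward(d)
    oracle <- ward_rescan_oracle(d)
    expect_identical(dend$merge, oracle$merge)
    expect_equal(dend$height, oracle$height, tolerance = 1e-10)
  }
})

test_that("both Ward dialects agree with the stats::hclust reference", {
  set.seed(101)
  for (trial in 1:10) {
    d <- random_dissimilarity(12)
    dend <- agglomerate_ward(d)
    h <- stats::hclust(stats::as.dist(d), method = "ward.D")
    expect_equal(dend$height, h$height, tolerance = 1e-10)
    for (k in c(2, 4, 8)) {
      mine <- cut_dendrogram(dend, k)
      ref <- stats::cutree(h, k)[dend$labels]
      expect_equal(mclust::adjustedRandIndex(mine, ref), 1)
    }
    dend2 <- agglomerate_ward(d, square_dissimilarity = TRUE)
    h2 <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    expect_equal(dend2$height, h2$height, tolerance = 1e-10)
  }
})

test_that("merge heights are non-decreasing (Ward reducibility)", {
  set.seed(102)
  for (trial in 1:20) {
    dend <- agglomerate_ward(random_dissimilarity(sample(4:15, 1)))
    expect_true(all(diff(dend$height) >= -1e-12))
  }
})

test_that("equal-distance ties break to the smallest cluster-index pair", {
  d <- matrix(1, 4, 4); diag(d) <- 0  # all distances tied
  dimnames(d) <- list(LETTERS[1:4], LETTERS[1:4])
  dend <- agglomerate_ward(d)
  expect_equal(dend$merge[1, ], c(-2L, -1L))
  # rerun is byte-identical
  expect_identical(dend, agglomerate_ward(d))
})

test_that("invalid dissimilarity inputs are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(agglomerate_ward(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(agglomerate_ward(neg), "non-negative")
  expect_error(agglomerate_ward(matrix(0, 1, 1)), "two leaves")
})

test_that("cutting undoes the last merges into k deterministic clusters", {
  set.seed(103)
  d <- random_dissimilarity(8)
  dend <- agglomerate_ward(d)
  all_one <- cut_dendrogram(dend, 1)
  expect_equal(unname(as.integer(all_one)), rep(1L, 8))
  singletons <- cut_dendrogram(dend, 8)
  expect_equal(sort(unique(as.integer(singletons))), 1:8)
  expect_error(cut_dendrogram(dend, 0), "between")
  expect_error(cut_dendrogram(dend, 9), "between")
  # k = n-1: exactly the first merge is joined
  pair <- cut_dendrogram(dend, 7)
  joined <- names(pair)[duplicated(pair) | duplicated(pair, fromLast = TRUE)]
  expect_setequal(match(joined, dend$labels), -dend$merge[1, ])
})

test_that("the planted 4-block dendrogram cut recovers the blocks", {
  cfg <- synthetic_config(n = 10000, seed = 77)
  co <- generate_cohort(cfg)
  m <- build_disease_matrix(co, criterion("chl2018"))
  dend <- agglomerate_ward(to_dissimilarity(association_matrix(m)))
  asg <- cut_dendrogram(dend, 4)
  gt <- ground_truth(cfg)
  expect_equal(mclust::adjustedRandIndex(asg[names(gt)], gt), 1)
  nm <- name_clusters(asg)
  expect_setequal(nm, c("cardiometabolic", "respiratory",
                        "digestive_bone_kidney", "mental_cancer"))
})

test_that("Newick export is parseable and recovers the topology", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  two <- export_newick(agglomerate_ward(d))
  expect_match(two, "^\\(A:0\\.4,B:0\\.4\\);$|^\\(B:0\\.4,A:0\\.4\\);$")

  set.seed(104)
  dd <- random_dissimilarity(9)
  dend <- agglomerate_ward(dd)
  tree <- ape::read.tree(text = export_newick(dend))
  expect_setequal(tree$tip.label, rownames(dd))
  ref <- ape::as.phylo(stats::as.hclust(dend))
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(ref)), 0,
               ignore_attr = TRUE)

  co <- generate_cohort(synthetic_config(n = 1000, seed = 1))
  m <- build_disease_matrix(co, criterion("chl2018"))
  full <- agglomerate_ward(to_dissimilarity(association_matrix(m)))
  tree26 <- ape::read.tree(text = export_newick(full))
  expect_length(tree26$tip.label, 26L)
})
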