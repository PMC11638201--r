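#' Pairwise 2x2 contingency table
#'
#' Exact joint counts of two binary disease columns: `a` both present,
#' `b` only the first, `c` only the second, `d` both absent.
#'
#' @param matrix A `disease_matrix`.
#' @param i,j Distinct disease codes.
#' @return A `contingency_2x2` list with fields `a`, `b`, `c`, `d`.
#' @export
contingency <- function(matrix, i, j) {
  stopifnot(inherits(matrix, "disease_matrix"))
  assert_known_codes(c(i, j))
  if (i == j) stop("contingency requires two distinct diseases",
                   call. = FALSE)
  x <- matrix[, i]; y <- matrix[, j]
  structure(list(a = sum(x == 1L & y == 1L),
                 b = sum(x == 1L & y == 0L),
                 c = sum(x == 0L & y == 1L),
                 d = sum(x == 0L & y == 0L)),
            class = "contingency_2x2")
}

#' Yule's Q association coefficient
#'
#' Q = (ad - bc) / (ad + bc), in \[-1, 1\]; 0 at independence, +/-1 when a
#' cross-product vanishes. When both cross products vanish (`ad + bc = 0`,
#' which covers every zero-marginal table) Q is undefined; a
#' Haldane-Anscombe continuity correction of +0.5 to all four cells is
#' applied for that table only, reported via a message and a `corrected`
#' attribute.
#'
#' @param tab A `contingency_2x2` (or list with fields `a`, `b`, `c`, `d`).
#' @return Numeric Q with logical attribute `corrected`.
#' @examples
#' yule_q(list(a = 30, b = 10, c = 20, d = 40))  # 0.714286
#' @export
yule_q <- function(tab) {
  a <- tab$a; b <- tab$b; cc <- tab$c; d <- tab$d
  stopifnot(all(c(a, b, cc, d) >= 0))
  if (a + b + cc + d == 0) {
    stop("Yule's Q is undefined for an all-zero table", call. = FALSE)
  }
  corrected <- (a * d + b * cc) == 0
  if (corrected) {
    message("yule_q: continuity correction (+0.5 to all cells) applied ",
            "to a degenerate table")
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  q <- (a * d - b * cc) / (a * d + b * cc)
  structure(q, corrected = corrected)
}

#' Pairwise Yule's Q association matrix
#'
#' Computes Q for every disease pair from the joint counts of the binary
#' columns. Diagonal is 1. Degenerate pairs (both cross products zero)
#' receive the per-pair continuity correction; the corrected pairs are
#' listed in the `corrected_pairs` attribute and summarised in a message.
#' A constant column (a disease everyone or no one has) makes Q
#' uninformative for every pair involving it and is rejected with an error
#' naming the disease; drop it or regenerate the cohort.
#'
#' @param matrix A `disease_matrix`.
#' @return 26 x 26 symmetric numeric matrix, class `association_matrix`,
#'   rows/columns in registry order.
#' @export
association_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "disease_matrix"))
  X <- unclass(matrix)
  attr(X, "criterion") <- NULL
  n_row <- nrow(X)
  hits <- colSums(X)
  constant <- colnames(X)[hits == 0L | hits == n_row]
  if (length(constant) > 0) {
    stop("constant disease column(s): ", paste(constant, collapse = ", "),
         "; exclude them or regenerate the cohort", call. = FALSE)
  }
  a <- crossprod(X)                      # both present
  b <- outer(hits, rep(1, ncol(X))) - a  # i present, j absent
  cmat <- t(b)
  d <- n_row - a - b - cmat
  denom <- a * d + b * cmat
  corrected <- denom == 0
  diag(corrected) <- FALSE
  if (any(corrected)) {
    a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
    cmat <- cmat + 0.5 * corrected; d <- d + 0.5 * corrected
    denom <- a * d + b * cmat
    pairs <- which(corrected & upper.tri(corrected), arr.ind = TRUE)
    message(sprintf(
      "association_matrix: continuity correction applied to %d pair(s)",
      nrow(pairs)))
  } else {
    pairs <- matrix(integer(0), 0, 2)
  }
  q <- (a * d - b * cmat) / denom
  diag(q) <- 1
  dimnames(q) <- list(colnames(X), colnames(X))
  structure(q, corrected_pairs = pairs,
            class = c("association_matrix", "matrix", "array"))
}

#' Convert association to dissimilarity
#'
#' d = 1 - Q off-diagonal, 0 on the diagonal; entries lie in \[0, 2\].
#'
#' @param assoc An `association_matrix`.
#' @return Symmetric numeric matrix, class `dissimilarity_matrix`.
#' @export
to_dissimilarity <- function(assoc) {
  stopifnot(inherits(assoc, "association_matrix"))
  d <- 1 - unclass(assoc)
  diag(d) <- 0
  attr(d, "corrected_pairs") <- NULL
  structure(d, class = c("dissimilarity_matrix", "matrix", "array"))
}

validate_dissimilarity <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("dissimilarity must be a square matrix", call. = FALSE)
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("dissimilarity matrix must be symmetric", call. = FALSE)
  }
  if (any(d < 0)) {
    stop("dissimilarity entries must be non-negative", call. = FALSE)
  }
  if (any(diag(d) != 0)) {
    stop("dissimilarity diagonal must be zero", call. = FALSE)
  }
  invisible(d)
}

#' Agglomerative Ward clustering via the Lance-Williams recurrence
#'
#' Merges the pair of clusters at minimal current distance and updates the
#' remaining distances with the Ward coefficients
#' `alpha_i = (n_i + n_k) / (n_i + n_j + n_k)`,
#' `alpha_j = (n_j + n_k) / (n_i + n_j + n_k)`,
#' `beta = -n_k / (n_i + n_j + n_k)`, `gamma = 0`. By default the
#' recurrence is applied to the supplied dissimilarities as-is (the
#' `ward.D` dialect); `square_dissimilarity = TRUE` applies it to squared
#' dissimilarities and reports square-rooted heights (`ward.D2` dialect).
#' 1 - Q is not Euclidean, so neither dialect is canonical; the choice is
#' exposed and defaulted.
#'
#' Ties in the minimal distance are broken deterministically: the pair
#' with the lexicographically smallest (cluster-index, cluster-index) in
#' the current active-cluster order is merged.
#'
#' @param d A `dissimilarity_matrix` (or plain symmetric matrix with zero
#'   diagonal), n >= 2, with dimnames as leaf labels.
#' @param square_dissimilarity Apply the recurrence to d^2 (default FALSE).
#' @return An `mm_dendrogram`: list with `merge` (hclust-style signed
#'   indices, n-1 rows), `height`, `sizes`, `labels`,
#'   `square_dissimilarity`. Heights are non-decreasing (Ward linkage is
#'   reducible).
#' @seealso [cut_dendrogram()], [export_newick()], [as.hclust.mm_dendrogram()]
#' @export
agglomerate_ward <- function(d, square_dissimilarity = FALSE) {
  d <- unclass(d)
  validate_dissimilarity(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least two leaves to cluster", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))

  D <- if (square_dissimilarity) d^2 else d
  diag(D) <- NA_real_
  ids <- -seq_len(n)        # hclust convention: negative = leaf
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  out_sizes <- integer(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- min(D, na.rm = TRUE)
    cand <- which(D == m, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pick <- cand[order(cand[, 1L], cand[, 2L])[1L], ]
    i <- pick[[1L]]; j <- pick[[2L]]

    ni <- sizes[i]; nj <- sizes[j]
    pair <- sort(c(ids[i], ids[j]))
    merge[step, ] <- pair
    height[step] <- if (square_dissimilarity) sqrt(D[i, j]) else D[i, j]
    out_sizes[step] <- ni + nj

    k_idx <- setdiff(seq_along(ids), c(i, j))
    if (length(k_idx) > 0) {
      nk <- sizes[k_idx]
      newd <- ((ni + nk) * D[i, k_idx] + (nj + nk) * D[j, k_idx] -
                 nk * D[i, j]) / (ni + nj + nk)
      D[i, k_idx] <- newd
      D[k_idx, i] <- newd
    }
    ids[i] <- step
    sizes[i] <- ni + nj
    D <- D[-j, -j, drop = FALSE]
    ids <- ids[-j]
    sizes <- sizes[-j]
  }
  structure(list(merge = merge, height = height, sizes = out_sizes,
                 labels = labels,
                 square_dissimilarity = square_dissimilarity),
            class = "mm_dendrogram")
}

#' @export
print.mm_dendrogram <- function(x, ...) {
  cat(sprintf("<mm_dendrogram> %d leaves, %d merges, heights %.3f..%.3f\n",
              length(x$labels), length(x$height),
              min(x$height), max(x$height)))
  invisible(x)
}

# leaf order for plotting, by recursive expansion of the merge tree
dendrogram_leaf_order <- function(dend) {
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(dend$merge[node, 1L]), expand(dend$merge[node, 2L]))
  }
  expand(nrow(dend$merge))
}

#' Convert to a base hclust object
#'
#' Allows plotting and interoperation with the standard dendrogram tooling
#' (`plot()`, `stats::as.dendrogram()`, ...).
#'
#' @param x An `mm_dendrogram`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @exportS3Method stats::as.hclust
as.hclust.mm_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height,
                 order = dendrogram_leaf_order(x), labels = x$labels,
                 method = if (x$square_dissimilarity) "ward.D2" else "ward.D",
                 call = match.call(), dist.method = "1 - Yule's Q"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' Undoes the last k - 1 merges: the clusters are the connected components
#' after replaying the first n - k merges. Cluster ids are assigned 1..k in
#' order of first appearance over the registry-ordered leaves, so the
#' labelling is deterministic.
#'
#' @param dend An `mm_dendrogram`.
#' @param k Number of clusters, 1 <= k <= n.
#' @return A `cluster_assignment`: named integer vector (leaf label ->
#'   cluster id) with attribute `k`.
#' @export
cut_dendrogram <- function(dend, k) {
  stopifnot(inherits(dend, "mm_dendrogram"))
  n <- length(dend$labels)
  if (k < 1 || k > n) {
    stop("k must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  comp <- -seq_len(n)            # component label per leaf, start singleton
  if (n - k >= 1) {
    for (step in seq_len(n - k)) {
      members <- function(node) if (node < 0) which(comp == node) else
        which(comp == node)
      left <- dend$merge[step, 1L]; right <- dend$merge[step, 2L]
      comp[comp %in% c(left, right)] <- step
    }
  }
  ids <- match(comp, unique(comp))   # first-appearance numbering
  structure(stats::setNames(as.integer(ids), dend$labels), k = as.integer(k),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> k = %d\n", attr(x, "k")))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Name clusters by seed-disease lists
#'
#' Attaches human-readable pattern names to a cut by matching each
#' cluster's membership against configurable seed lists (default: the four
#' canonical patterns). A cluster takes the name of the seed list with
#' which it shares the most diseases; clusters with no overlap keep
#' `cluster_<id>`.
#'
#' @param assignment A `cluster_assignment`.
#' @param seeds Named list of code vectors; default
#'   [default_pattern_seeds()].
#' @return Character vector: cluster id -> name.
#' @export
name_clusters <- function(assignment, seeds = default_pattern_seeds()) {
  k <- attr(assignment, "k")
  out <- paste0("cluster_", seq_len(k))
  for (cl in seq_len(k)) {
    members <- names(assignment)[assignment == cl]
    overlap <- vapply(seeds, function(s) length(intersect(s, members)),
                      integer(1))
    if (max(overlap) > 0) out[cl] <- names(seeds)[which.max(overlap)]
  }
  out
}

#' Canonical pattern seed lists
#'
#' Seed diseases for naming the four recurrent multimorbidity patterns:
#' cardiometabolic, respiratory, digestive-bone-kidney and mental-cancer.
#'
#' @return Named list of disease-code vectors.
#' @export
default_pattern_seeds <- function() {
  list(
    cardiometabolic = c("hypertension", "diabetes", "ami", "angina",
                        "stroke_tia"),
    respiratory = c("pulm_heart", "tuberculosis", "emphysema",
                    "chronic_bronchitis", "copd", "asthma"),
    digestive_bone_kidney = c("hepatitis_cirrhosis", "peptic_ulcer",
                              "gallstones", "ckd", "osteoporosis",
                              "fracture", "rheumatoid_arthritis"),
    mental_cancer = c("depression", "anxiety", "neurasthenia",
                      "other_mental", "brain_injury", "cancer")
  )
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are differences of merge heights (leaves sit at height
#' 0), so the tree drawn from the string has node depths equal to the Ward
#' merge heights.
#'
#' @param dend An `mm_dendrogram`.
#' @return A single Newick string terminated by ";".
#' @export
export_newick <- function(dend) {
  stopifnot(inherits(dend, "mm_dendrogram"))
  node_height <- function(node) if (node < 0) 0 else dend$height[node]
  render <- function(node, parent_h) {
    len <- parent_h - node_height(node)
    if (node < 0) {
      sprintf("%s:%.10g", dend$labels[-node], len)
    } else {
      sprintf("(%s,%s):%.10g",
              render(dend$merge[node, 1L], dend$height[node]),
              render(dend$merge[node, 2L], dend$height[node]), len)
    }
  }
  root <- nrow(dend$merge)
  h <- dend$height[root]
  sprintf("(%s,%s);",
          render(dend$merge[root, 1L], h),
          render(dend$merge[root, 2L], h))
}

#' Dendrogram merge table
#'
#' @param dend An `mm_dendrogram`.
#' @return Tibble with columns `step`, `left`, `right` (hclust-style signed
#'   indices), `height`, `size`.
#' @export
merge_table <- function(dend) {
  stopifnot(inherits(dend, "mm_dendrogram"))
  tibble::tibble(step = seq_along(dend$height),
                 left = dend$merge[, 1L], right = dend$merge[, 2L],
                 height = dend$height, size = dend$sizes)
}
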