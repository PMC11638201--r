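# Independent oracles and small fixture builders used across the suite.

# Naive O(n^3) re-scan Ward clustering: at every step the distance between
# two clusters is recomputed from the *original* dissimilarity matrix with
# the closed-form Ward/ESS expression
#   D(A, B) = nA nB / (nA + nB) *
#             (2 S_AB / (nA nB) - S_AA / nA^2 - S_BB / nB^2),
# which never uses the incremental Lance-Williams update the implementation
# relies on. Same tie-break: lexicographically smallest active-pair index.
ward_rescan_oracle <- function(d, square = FALSE) {
  work <- if (square) d^2 else d
  n <- nrow(work)
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  cluster_dist <- function(A, B) {
    nA <- length(A); nB <- length(B)
    sAB <- sum(work[A, B, drop = FALSE])
    sAA <- sum(work[A, A, drop = FALSE])
    sBB <- sum(work[B, B, drop = FALSE])
    nA * nB / (nA + nB) * (2 * sAB / (nA * nB) - sAA / nA^2 - sBB / nB^2)
  }
  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dij <- cluster_dist(clusters[[i]], clusters[[j]])
        if (is.null(best) || dij < best$d - 1e-12) {
          best <- list(i = i, j = j, d = dij)
        }
      }
    }
    merge[step, ] <- sort(c(ids[best$i], ids[best$j]))
    height[step] <- if (square) sqrt(best$d) else best$d
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    ids[best$i] <- step
    clusters[[best$j]] <- NULL
    ids <- ids[-best$j]
  }
  list(merge = merge, height = height)
}

random_dissimilarity <- function(n) {
  d <- matrix(0, n, n)
  d[lower.tri(d)] <- runif(n * (n - 1) / 2, 0.05, 2)
  d <- d + t(d)
  rownames(d) <- colnames(d) <- paste0("L", seq_len(n))
  d
}

# Wrap a raw 0/1 matrix as a disease_matrix (first ncol registry codes).
as_dm <- function(values, cri = criterion("chl2018")) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  colnames(values) <- disease_codes()[seq_len(ncol(values))]
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("P%04d", seq_len(nrow(values)))
  }
  structure(values, criterion = cri,
            class = c("disease_matrix", "matrix", "array"))
}

random_disease_matrix <- function(n, p = 0.15, ncol = 26) {
  as_dm(matrix(rbinom(n * ncol, 1, p), n, ncol))
}

# Minimal valid hand-built records (all flags FALSE unless overridden).
make_records <- function(n = 3) {
  rec <- tibble::tibble(
    participant_id = sprintf("H%03d", seq_len(n)),
    sbp = 118 + seq_len(n), dbp = 72 + (seq_len(n) %% 3),
    self_reported_hypertension = FALSE,
    sex = rep_len(c("male", "female"), n),
    age = 40 + seq_len(n))
  for (code in disease_codes(include_hypertension = FALSE)) {
    rec[[code]] <- FALSE
  }
  rec
}
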