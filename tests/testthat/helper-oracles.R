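# Independent oracles used by the tests. These deliberately avoid the code
# paths they check: the alignment oracle enumerates alignments instead of
# running dynamic programming, the clustering oracle is a hand-rolled
# union-find, and superposition optimality is bounded by Monte-Carlo
# sampling of random rigid transforms.

# Brute-force optimal local alignment score: enumerate every strictly
# increasing matching between positions of a and b; between consecutive
# matched pairs each side's unmatched run is one affine gap
# (open + extend * length). Feasible for sequences up to length ~8.
brute_local_score <- function(a, b, scheme = defaultScheme()) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- scheme@matrix
  go <- scheme@gapOpen
  ge <- scheme@gapExtend
  best <- 0
  for (k in seq_len(min(length(A), length(B)))) {
    sa <- utils::combn(length(A), k, simplify = FALSE)
    sb <- utils::combn(length(B), k, simplify = FALSE)
    for (ia in sa) {
      for (ib in sb) {
        sc <- sum(m[cbind(A[ia], B[ib])])
        if (k > 1) {
          ga <- diff(ia) - 1L
          gb <- diff(ib) - 1L
          sc <- sc - sum((go + ge * ga)[ga > 0]) - sum((go + ge * gb)[gb > 0])
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Union-find connected components over ids given an edge list (2-col matrix)
uf_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1]); rb <- find(edges[e, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# Uniform random proper rotation (quaternion method)
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Minimum RMSD over nRot random proper rotations (translation optimal for
# each, i.e. centroids matched); a Monte-Carlo upper bound on the optimum.
mc_min_rmsd <- function(P, Q, nRot = 10000L) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  RT <- matrix(0, 3, 3L * nRot)
  for (t in seq_len(nRot))
    RT[, (3L * t - 2L):(3L * t)] <- random_rotation()
  X <- Pc %*% RT                                  # N x 3*nRot
  D <- (X - Qc[, rep(1:3, nRot)])^2
  cs <- colSums(D)
  block <- cs[seq(1, length(cs), 3)] + cs[seq(2, length(cs), 3)] +
    cs[seq(3, length(cs), 3)]
  sqrt(min(block) / nrow(P))
}

random_protein <- function(n) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

shuffle_protein <- function(seq) {
  paste(sample(strsplit(seq, "")[[1]]), collapse = "")
}

# Small fixture collection shared across pipeline tests (built once)
.fixture_cache <- new.env(parent = emptyenv())
small_collection <- function() {
  if (is.null(.fixture_cache$coll)) {
    dir <- file.path(tempdir(), "tpsmine-small-coll")
    .fixture_cache$coll <- makeFixtureCollection(dir, nGenomes = 2L, seed = 11L)
  }
  .fixture_cache$coll
}
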