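#' @include structure-io.R
NULL

#' Optimal rigid superposition of paired point sets (Kabsch)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD between
#' \code{P \%*\% R + t} and \code{Q} over all rigid transforms. Reflections
#' are suppressed by sign-correcting the smallest singular direction, so the
#' mirror image of a chiral point set keeps a positive RMSD.
#'
#' @param P,Q n x 3 matrices of paired coordinates (n >= 3).
#' @return list with \code{rotation} (3 x 3, det +1), \code{translation}
#'   (length 3) and \code{rmsd}.
#' @examples
#' P <- matrix(rnorm(30), 10, 3)
#' fit <- kabsch(P, sweep(P, 2, c(1, 2, 3), "+"))
#' fit$rmsd  # 0
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("P and Q must have the same dimensions")
  if (nrow(P) < 3L) stop("at least 3 paired points are required")
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  C <- crossprod(Pc, Qc)                       # 3 x 3 covariance
  sv <- svd(C)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)   # row-vector convention: P %*% R
  t <- as.numeric(cQ - cP %*% R)
  diff <- Pc %*% R - Qc
  list(rotation = R, translation = t,
       rmsd = sqrt(mean(rowSums(diff^2))))
}

#' Apply a superposition to coordinates
#'
#' @param xyz n x 3 coordinate matrix.
#' @param sup a [Superposition-class] or a list with \code{rotation} and
#'   \code{translation}.
#' @return the transformed n x 3 matrix.
#' @export
applySuperposition <- function(xyz, sup) {
  R <- if (methods::is(sup, "Superposition")) rotationMatrix(sup) else sup$rotation
  t <- if (methods::is(sup, "Superposition")) translationVector(sup) else sup$translation
  sweep(as.matrix(xyz) %*% R, 2, t, "+")
}

#' TM-score distance scale d0
#'
#' \eqn{d_0(L) = 1.24 (L - 15)^{1/3} - 1.8} Angstrom for L > 21, clamped to
#' 0.5 Angstrom for shorter normalization lengths.
#'
#' @param L normalization length (>= 1).
#' @return d0 in Angstrom.
#' @export
tmD0 <- function(L) {
  stopifnot(L >= 1)
  ifelse(L > 21, pmax(1.24 * (L - 15)^(1/3) - 1.8, 0.5), 0.5)
}

# squared distances between paired rows after superposing on a subset
.pair_dists <- function(coordsA, coordsB, pairs, fit) {
  ta <- applySuperposition(coordsA[pairs[, 1], , drop = FALSE], fit)
  sqrt(rowSums((ta - coordsB[pairs[, 2], , drop = FALSE])^2))
}

#' TM-score of an aligned residue pairing
#'
#' \eqn{TM = \max (1/L_{norm}) \sum_i 1/(1 + (d_i/d_0(L_{norm}))^2)},
#' maximized over rigid superpositions fitted on subsets of the pairing by
#' the standard iterative protocol: fit on the current subset, score all
#' pairs, re-select the pairs closer than d0, and keep the best score seen.
#'
#' @param pairs two-column matrix of (row in A, row in B) aligned indices.
#' @param coordsA,coordsB coordinate matrices of the two models.
#' @param lNorm normalization length (conventionally the reference length).
#' @return TM-score in (0, 1].
#' @export
tmScore <- function(pairs, coordsA, coordsB, lNorm) {
  stopifnot(nrow(pairs) >= 1L, lNorm >= 1)
  d0 <- tmD0(lNorm)
  score_of <- function(d) sum(1 / (1 + (d / d0)^2)) / lNorm
  if (nrow(pairs) < 3L) {
    # too few pairs for a meaningful fit: superpose by centroid only
    a <- coordsA[pairs[, 1], , drop = FALSE]
    b <- coordsB[pairs[, 2], , drop = FALSE]
    d <- sqrt(rowSums((sweep(a, 2, colMeans(a) - colMeans(b)) - b)^2))
    return(min(1, score_of(d)))
  }
  subset <- seq_len(nrow(pairs))
  best <- 0
  seen <- character(0)
  for (iter in seq_len(20L)) {
    fit <- kabsch(coordsA[pairs[subset, 1], , drop = FALSE],
                  coordsB[pairs[subset, 2], , drop = FALSE])
    d <- .pair_dists(coordsA, coordsB, pairs, fit)
    best <- max(best, score_of(d))
    newSubset <- which(d < d0)
    if (length(newSubset) < 3L)
      newSubset <- order(d)[seq_len(min(3L, nrow(pairs)))]
    key <- paste(newSubset, collapse = ",")
    if (key %in% seen) break
    seen <- c(seen, key)
    subset <- newSubset
  }
  min(1, best)
}

# run one seed of the iterative alignment; returns pairs or NULL
.iterate_alignment <- function(pairs, coordsA, coordsB, d0, gap, maxIter) {
  seen <- character(0)
  for (iter in seq_len(maxIter)) {
    if (nrow(pairs) < 3L) return(NULL)
    fit <- kabsch(coordsA[pairs[, 1], , drop = FALSE],
                  coordsB[pairs[, 2], , drop = FALSE])
    ta <- applySuperposition(coordsA, fit)
    d2 <- outer(rowSums(ta^2), rowSums(coordsB^2), "+") - 2 * tcrossprod(ta, coordsB)
    S <- 1 / (1 + pmax(d2, 0) / d0^2)
    newPairs <- .align_global_dp(S, gap)
    key <- paste(newPairs[, 1], newPairs[, 2], collapse = ";")
    if (key %in% seen || identical(newPairs, pairs)) return(newPairs)
    seen <- c(seen, key)
    pairs <- newPairs
  }
  pairs
}

#' Sequence-independent structure alignment
#'
#' Aligns two Calpha models without any sequence prior. Initial pairings are
#' taken from gapless threadings of A onto B at every offset (stride 5) and
#' from pairing the two N-terminal 30-mers. Each seed is refined by
#' iterating: Kabsch fit on the current pairs, residue-residue similarity
#' \eqn{S_{ij} = 1/(1 + (d_{ij}/d_0)^2)}, global dynamic programming with a
#' flat gap penalty, until the pair set repeats or \code{maxIter} rounds.
#' The refined alignment with the highest TM-score (normalized by the
#' reference length, \code{nResidues(B)}) wins. The reported RMSD is the
#' least-squares optimum over the full final pair set. Deterministic for
#' fixed inputs.
#'
#' @param A mobile [StructureModel-class] (>= 20 residues).
#' @param B reference [StructureModel-class] (>= 20 residues).
#' @param gapPenalty flat DP gap penalty (default 0.6).
#' @param stride threading-seed offset stride (default 5).
#' @param maxIter maximum refinement rounds per seed (default 30).
#' @param seedLen length of the N-terminal fragment seed (default 30).
#' @return a [Superposition-class] mapping A onto B.
#' @export
structureAlign <- function(A, B, gapPenalty = 0.6, stride = 5L, maxIter = 30L,
                           seedLen = 30L) {
  n <- nResidues(A); m <- nResidues(B)
  if (n < 20L || m < 20L)
    stop("both models need at least 20 residues (have ", n, " and ", m, ")")
  coordsA <- caCoords(A); coordsB <- caCoords(B)
  d0 <- tmD0(m)
  minOv <- 20L

  seeds <- list()
  for (o in seq.int(-(n - minOv), m - minOv, by = stride)) {
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1L & j <= m
    seeds[[length(seeds) + 1L]] <- cbind(i[ok], j[ok])
  }
  s <- min(seedLen, n, m)
  seeds[[length(seeds) + 1L]] <- cbind(seq_len(s), seq_len(s))

  best <- NULL; bestTm <- -Inf
  for (seed in seeds) {
    pairs <- .iterate_alignment(seed, coordsA, coordsB, d0, gapPenalty, maxIter)
    if (is.null(pairs) || nrow(pairs) < 3L) next
    tm <- tmScore(pairs, coordsA, coordsB, m)
    if (tm > bestTm) { bestTm <- tm; best <- pairs }
  }
  if (is.null(best)) stop("structure alignment failed: no seed converged")

  fit <- kabsch(coordsA[best[, 1], , drop = FALSE],
                coordsB[best[, 2], , drop = FALSE])
  colnames(best) <- c("i", "j")
  new("Superposition", rotation = fit$rotation, translation = fit$translation,
      pairs = best, rmsd = fit$rmsd, tmScore = bestTm, lNorm = as.integer(m))
}

#' Screen a candidate model against reference TPS structures
#'
#' Aligns the candidate to every reference with [structureAlign()] and
#' reports all superpositions sorted by decreasing TM-score. The candidate
#' passes the screen when its best TM-score reaches \code{tmMin} (0.5 by
#' default, the conventional same-fold criterion).
#'
#' @param candidate a [StructureModel-class].
#' @param refs named list of reference [StructureModel-class] objects
#'   (e.g. class I, class IB and class IC TPS structures).
#' @param tmMin pass threshold on the best TM-score.
#' @return named list of [Superposition-class], sorted by TM-score
#'   descending, with attribute \code{"pass"} (logical).
#' @export
screenByStructure <- function(candidate, refs, tmMin = 0.5) {
  stopifnot(length(refs) >= 1L)
  if (is.null(names(refs)))
    names(refs) <- vapply(refs, modelId, character(1))
  sups <- lapply(refs, function(r) structureAlign(candidate, r))
  tm <- vapply(sups, tmScoreOf, numeric(1))
  sups <- sups[order(-tm)]
  attr(sups, "pass") <- max(tm) >= tmMin
  sups
}

#' Serialize a superposition as JSON
#'
#' @param sup a [Superposition-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSuperpositionJson <- function(sup, path) {
  jsonlite::write_json(list(
    rotation = rotationMatrix(sup),
    translation = translationVector(sup),
    pairs = alignedPairs(sup),
    rmsd = rmsdOf(sup),
    tm_score = tmScoreOf(sup),
    l_norm = sup@lNorm), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
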