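#' @include align.R
NULL

#' Alignment-identity distance matrix
#'
#' \eqn{d(i, j) = 1 - } identity fraction of the optimal pairwise local
#' alignment, clamped to [0, 1]; pairs with no positive-scoring alignment
#' get distance 1. Optionally applies the Kimura correction for multiple
#' substitutions, \eqn{d' = -\ln(1 - d - d^2/5)}.
#'
#' @param seqs named character vector (or \code{AAStringSet}) of >= 2
#'   protein sequences.
#' @param scheme a [ScoringScheme-class].
#' @param correction \code{"none"} (default) or \code{"kimura"}.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distanceMatrix <- function(seqs, scheme = defaultScheme(),
                           correction = c("none", "kimura")) {
  correction <- match.arg(correction)
  if (methods::is(seqs, "XStringSet"))
    seqs <- stats::setNames(as.character(seqs), names(seqs))
  stopifnot(length(seqs) >= 2L)
  ids <- names(seqs)
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      hit <- smithWaterman(seqs[[i]], seqs[[j]], scheme)
      dij <- if (rawScore(hit) > 0L)
        min(1, max(0, 1 - identityFraction(hit))) else 1
      if (correction == "kimura" && dij < 0.85)
        dij <- -log(1 - dij - dij^2 / 5)
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Q-matrix agglomeration with the usual
#' branch-length formulas). Negative branch lengths are clamped to zero with
#' the deficit transferred to the sibling branch, preserving path lengths
#' through the parent node. On additive matrices the generating topology and
#' branch lengths are recovered exactly.
#'
#' @param dm symmetric distance matrix (>= 3 taxa) with taxon ids as
#'   dimnames.
#' @return an \code{ape} \code{phylo} tree (unrooted).
#' @export
neighborJoining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix must be symmetric")
  tree <- ape::nj(dm)

  # clamp negative branch lengths; move the deficit to the sibling edge
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    parent <- tree$edge[e, 1]
    sib <- setdiff(which(tree$edge[, 1] == parent), e)
    deficit <- tree$edge.length[e]
    tree$edge.length[e] <- 0
    if (length(sib))
      tree$edge.length[sib[1]] <- tree$edge.length[sib[1]] + deficit
  }
  tree
}

# quote a Newick label if it contains structural characters
.nwk_label <- function(x) {
  ifelse(grepl("[][ \t():;,']", x),
         paste0("'", gsub("'", "''", x), "'"),
         x)
}

#' Serialize a tree as Newick
#'
#' Branch lengths are written with 6 decimal places; labels containing
#' spaces or Newick structural characters are single-quoted.
#'
#' @param tree an \code{ape} \code{phylo} object.
#' @param path optional output file; when NULL the string is returned.
#' @return the Newick string (invisibly when written to a file).
#' @export
writeNewick <- function(tree, path = NULL) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])

  render <- function(node) {
    edges <- kids[[as.character(node)]]
    if (is.null(edges)) return(.nwk_label(tree$tip.label[node]))
    parts <- vapply(edges, function(e) {
      child <- tree$edge[e, 2]
      sprintf("%s:%.6f", render(child), tree$edge.length[e])
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(render(root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}
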