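#' @include align.R
NULL

#' Pairwise E-value table over candidates
#'
#' Entry (i, j) is the smaller of the two directional E-values of the optimal
#' local alignment between candidates i and j (each computed against a
#' single-sequence database); the diagonal is 0.
#'
#' @param cands named character vector of candidate protein sequences.
#' @param scheme a [ScoringScheme-class].
#' @return symmetric numeric matrix with candidate ids as dimnames.
#' @export
pairwiseEvalues <- function(cands, scheme = defaultScheme()) {
  stopifnot(length(cands) >= 1L)
  ids <- names(cands)
  if (is.null(ids)) stop("candidates must be named")
  n <- length(cands)
  E <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n == 1L) return(E)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      hit <- smithWaterman(cands[[i]], cands[[j]], scheme,
                           queryId = ids[i], subjectId = ids[j])
      s <- rawScore(hit)
      eij <- eValue(s, nchar(cands[[i]]), nchar(cands[[j]]), scheme)
      eji <- eValue(s, nchar(cands[[j]]), nchar(cands[[i]]), scheme)
      E[i, j] <- E[j, i] <- min(eij, eji)
    }
  }
  E
}

#' Cluster candidates into types by pairwise E-value
#'
#' Builds the graph whose edges join candidate pairs with E-value strictly
#' below the threshold and takes its connected components (single linkage).
#' Clusters are labelled \code{type-1}, \code{type-2}, ... in order of
#' decreasing size, ties broken by the lexicographically smallest member.
#'
#' @param evalueTable symmetric E-value matrix from [pairwiseEvalues()].
#' @param threshold E-value threshold (default 0.1).
#' @return a [TypePartition-class].
#' @export
clusterTypes <- function(evalueTable, threshold = 0.1) {
  stopifnot(threshold > 0)
  ids <- rownames(evalueTable)
  adj <- (evalueTable < threshold)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  clusters <- split(ids, comp$membership)
  clusters <- lapply(clusters, sort)
  ord <- order(-lengths(clusters), vapply(clusters, `[`, character(1), 1L))
  clusters <- clusters[ord]
  names(clusters) <- sprintf("type-%d", seq_along(clusters))
  new("TypePartition", clusters = clusters, threshold = threshold)
}

#' Find homologs of a type representative in a protein database
#'
#' Thin wrapper over [searchHomologs()] with the homolog-census default
#' cutoff of 1e-5. When database headers carry an organism token in square
#' brackets (\code{"id [Genus species]"}) a per-species deduplicated count is
#' attached as the \code{"speciesCounts"} attribute.
#'
#' @param representative protein sequence of the type representative.
#' @param proteinDb named character vector or \code{AAStringSet}.
#' @param scheme a [ScoringScheme-class].
#' @param eMax homolog E-value cutoff (default 1e-5).
#' @param queryId id recorded in the hit table.
#' @return hit data.frame as in [searchHomologs()].
#' @export
findHomologs <- function(representative, proteinDb, scheme = defaultScheme(),
                         eMax = 1e-5, queryId = "representative") {
  hits <- searchHomologs(representative, proteinDb, scheme, eMax = eMax,
                         queryId = queryId)
  org <- regmatches(hits$sseqid, regexpr("\\[[^]]+\\]", hits$sseqid))
  if (length(org)) {
    species <- table(gsub("\\[|\\]", "", org))
    attr(hits, "speciesCounts") <- species
  }
  hits
}

#' Write a type-membership table as TSV
#'
#' @param partition a [TypePartition-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTypesTsv <- function(partition, path) {
  cl <- typeClusters(partition)
  df <- data.frame(candidate_id = unlist(cl, use.names = FALSE),
                   type_label = rep(names(cl), lengths(cl)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
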