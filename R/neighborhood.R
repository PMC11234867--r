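#' @include align.R
NULL

.DEFAULT_HYPOTHETICAL_KEYWORDS <- c("hypothetical", "uncharacterized",
                                    "unknown function", "DUF")

#' Find E-IDS anchor genes in a genome
#'
#' Every gene whose best local-alignment hit against the E-IDS reference set
#' has E-value below \code{eMax} becomes an anchor. E-values use the total
#' residue count of the reference set as the database size.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param eidsRefs named character vector (or \code{AAStringSet}) of
#'   E-isoprenyl diphosphate synthase reference protein sequences.
#' @param scheme a [ScoringScheme-class].
#' @param eMax anchor E-value cutoff (default 1e-5).
#' @return data.frame of anchors sorted by contig then rank, with columns
#'   \code{gene_id}, \code{contig_id}, \code{rank}, \code{best_ref},
#'   \code{evalue}, \code{bitscore}.
#' @export
findAnchors <- function(genome, eidsRefs, scheme = defaultScheme(),
                        eMax = 1e-5) {
  if (methods::is(eidsRefs, "XStringSet"))
    eidsRefs <- stats::setNames(as.character(eidsRefs), names(eidsRefs))
  stopifnot(length(eidsRefs) >= 1L)
  g <- geneTable(genome)
  out <- list()
  for (i in seq_len(nrow(g))) {
    if (!nzchar(g$protein_seq[i])) next
    h <- searchHomologs(g$protein_seq[i], eidsRefs, scheme, eMax = eMax,
                        queryId = g$gene_id[i])
    if (nrow(h)) {
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g$gene_id[i], contig_id = g$contig_id[i], rank = g$rank[i],
        best_ref = h$sseqid[1], evalue = h$evalue[1], bitscore = h$bitscore[1],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), contig_id = character(),
                      rank = integer(), best_ref = character(),
                      evalue = numeric(), bitscore = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$contig_id, res$rank), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the gene-count window around an anchor
#'
#' Returns the genes on the anchor's contig whose rank lies within \code{k}
#' of the anchor's rank, excluding the anchor itself; the window is truncated
#' at contig ends and never crosses contigs. \code{k = Inf} disables the
#' window (all other genes on the contig are returned).
#'
#' @param genome a [GenomeAnnotation-class].
#' @param anchor one row of the [findAnchors()] table (or a list with
#'   \code{gene_id}, \code{contig_id}, \code{rank}).
#' @param k window half-width in genes (default 10).
#' @return data.frame of neighbor candidates: the gene columns plus
#'   \code{offset} (signed rank difference from the anchor),
#'   \code{anchor_gene_id} and \code{anchor_evalue}.
#' @export
extractWindow <- function(genome, anchor, k = 10) {
  stopifnot(k >= 1)
  g <- geneTable(genome)
  sub <- g[g$contig_id == anchor$contig_id, , drop = FALSE]
  off <- sub$rank - anchor$rank
  keep <- off != 0L & abs(off) <= k
  res <- sub[keep, , drop = FALSE]
  res$offset <- off[keep]
  res$anchor_gene_id <- anchor$gene_id
  res$anchor_evalue <- if (!is.null(anchor$evalue)) anchor$evalue else NA_real_
  res <- res[order(res$offset), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Keep hypothetical-protein candidates
#'
#' Retains candidates whose product annotation matches any keyword
#' (case-insensitively, fixed strings) or whose product is empty, and flags
#' them \code{is_hypothetical}.
#'
#' @param cands candidate data.frame from [extractWindow()].
#' @param keywords character vector of annotation keywords; the default is
#'   hypothetical / uncharacterized / unknown function / DUF.
#' @return the retained subset with an \code{is_hypothetical} column.
#' @export
filterHypothetical <- function(cands,
                               keywords = .DEFAULT_HYPOTHETICAL_KEYWORDS) {
  stopifnot(length(keywords) >= 1L)
  if (!nrow(cands)) {
    cands$is_hypothetical <- logical(0)
    return(cands)
  }
  hit <- !nzchar(cands$product)
  for (kw in keywords)
    hit <- hit | grepl(kw, cands$product, ignore.case = TRUE, fixed = FALSE)
  res <- cands[hit, , drop = FALSE]
  res$is_hypothetical <- rep(TRUE, nrow(res))
  rownames(res) <- NULL
  res
}
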