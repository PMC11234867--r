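#' @include superpose.R align.R
NULL

#' Catalytic residue reference
#'
#' Labels the catalytic residues of a reference TPS structure (e.g. the
#' DDXXD / NSE-DTE aspartates of a class I enzyme) by residue number.
#'
#' @param refModelId id of the reference structure model.
#' @param resIndex residue numbers of the catalytic residues.
#' @param aa one-letter codes (optional, for bookkeeping).
#' @param role free-text role labels (optional).
#' @return data.frame with attribute \code{refModelId}.
#' @export
catalyticReference <- function(refModelId, resIndex, aa = NA, role = NA) {
  df <- data.frame(res_index = as.integer(resIndex), aa = aa, role = role,
                   stringsAsFactors = FALSE)
  attr(df, "refModelId") <- refModelId
  df
}

#' Candidate residues sterically close to the reference active site
#'
#' Transforms the candidate Calpha trace with the superposition and reports
#' every candidate residue whose transformed Calpha lies within
#' \code{cutoff} Angstrom (closed bound) of any catalytic-reference Calpha.
#'
#' @param cand candidate [StructureModel-class].
#' @param ref reference [StructureModel-class].
#' @param sup the [Superposition-class] of \code{cand} onto \code{ref}.
#' @param catRef a [catalyticReference()] table for \code{ref}.
#' @param cutoff Calpha-Calpha distance cutoff in Angstrom (default 5.0).
#' @return data.frame (\code{res_index}, \code{aa}, \code{min_distance})
#'   sorted by residue number.
#' @export
mapProximalResidues <- function(cand, ref, sup, catRef, cutoff = 5.0) {
  at <- match(catRef$res_index, residueIndices(ref))
  if (anyNA(at))
    stop("catalytic residue(s) missing from reference model ", modelId(ref),
         ": ", paste(catRef$res_index[is.na(at)], collapse = ", "))
  refXyz <- caCoords(ref)[at, , drop = FALSE]
  candXyz <- applySuperposition(caCoords(cand), sup)
  d2 <- outer(rowSums(candXyz^2), rowSums(refXyz^2), "+") -
    2 * tcrossprod(candXyz, refXyz)
  mind <- sqrt(pmax(apply(d2, 1, min), 0))
  keep <- which(mind <= cutoff)
  out <- data.frame(res_index = residueIndices(cand)[keep],
                    aa = residueLetters(cand)[keep],
                    min_distance = mind[keep], stringsAsFactors = FALSE)
  out <- out[order(out$res_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compress proximal residues into motif strings
#'
#' Residues whose successive residue numbers differ by at most
#' \code{maxGap + 1} are merged into one motif; interior positions that are
#' not in the input are rendered as \code{X}. For example residues
#' \{338:R, 341:K, 342:D\} give the pattern \code{"RXXKD"}.
#'
#' @param proximal data.frame with \code{res_index} and \code{aa} columns
#'   (e.g. from [mapProximalResidues()]).
#' @param maxGap largest number of interior skipped positions that still
#'   merges two residues into one motif (default 3).
#' @return data.frame with \code{pattern}, \code{start}, \code{end} and a
#'   \code{positions} list-column of the contributing residue numbers.
#' @examples
#' extractMotifs(data.frame(res_index = c(338, 341, 342),
#'                          aa = c("R", "K", "D")))$pattern  # "RXXKD"
#' @export
extractMotifs <- function(proximal, maxGap = 3L) {
  if (!nrow(proximal))
    return(data.frame(pattern = character(), start = integer(),
                      end = integer()))
  proximal <- proximal[order(proximal$res_index), , drop = FALSE]
  idx <- proximal$res_index
  grp <- cumsum(c(1L, diff(idx) > maxGap + 1L))
  rows <- lapply(split(seq_along(idx), grp), function(k) {
    pos <- idx[k]
    span <- seq.int(min(pos), max(pos))
    pat <- rep("X", length(span))
    pat[match(pos, span)] <- proximal$aa[k]
    data.frame(pattern = paste(pat, collapse = ""),
               start = min(pos), end = max(pos), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$positions <- unname(split(idx, grp))
  rownames(out) <- NULL
  out
}

#' Star multiple alignment onto an anchor sequence
#'
#' Aligns every homolog pairwise (global, affine gaps) to the anchor and
#' projects each alignment onto the anchor's columns: positions inserted
#' relative to the anchor are dropped, so every row has exactly one symbol
#' (residue letter or \code{"-"}) per anchor position.
#'
#' @param anchorSeq anchor protein sequence.
#' @param homologSeqs named character vector (or \code{AAStringSet}) of
#'   homolog sequences.
#' @param scheme a [ScoringScheme-class].
#' @return character matrix, one row per homolog, one column per anchor
#'   position.
#' @export
starMsa <- function(anchorSeq, homologSeqs, scheme = defaultScheme()) {
  if (methods::is(homologSeqs, "XStringSet"))
    homologSeqs <- stats::setNames(as.character(homologSeqs), names(homologSeqs))
  stopifnot(length(homologSeqs) >= 1L)
  .check_protein(anchorSeq, "anchor", rownames(scheme@matrix))
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(homologSeqs),
    subject = Biostrings::AAString(anchorSeq),
    type = "global",
    substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gapOpen, gapExtension = scheme@gapExtend)
  L <- nchar(anchorSeq)
  rows <- matrix("-", length(homologSeqs), L,
                 dimnames = list(names(homologSeqs), NULL))
  hs <- as.character(Biostrings::alignedPattern(pa))
  as_ <- as.character(Biostrings::alignedSubject(pa))
  for (r in seq_along(hs)) {
    h <- strsplit(hs[r], "")[[1]]
    a <- strsplit(as_[r], "")[[1]]
    anchorCols <- a != "-"
    rows[r, ] <- h[anchorCols]
  }
  rows
}

#' Per-column conservation of a star alignment
#'
#' Information content \eqn{IC = \log_2 20 - H} of each column, with the
#' Shannon entropy H computed over the 20 canonical letters of the non-gap
#' symbols (gaps and X excluded). Letter heights are frequency times IC, the
#' quantity drawn in sequence logos. All-gap columns get IC 0.
#'
#' @param msa character matrix from [starMsa()].
#' @param pseudocount count added to every letter before computing
#'   frequencies (default 0).
#' @return list with \code{ic} (per-column bits) and \code{heights}
#'   (20 x ncol matrix of letter heights).
#' @export
columnConservation <- function(msa, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  L <- ncol(msa)
  ic <- numeric(L)
  heights <- matrix(0, 20, L, dimnames = list(.AA20, NULL))
  for (j in seq_len(L)) {
    col <- msa[, j]
    col <- col[col %in% .AA20]
    cnt <- table(factor(col, levels = .AA20)) + pseudocount
    tot <- sum(cnt)
    if (tot == 0) next
    p <- as.numeric(cnt) / tot
    H <- -sum(ifelse(p > 0, p * log2(p), 0))
    ic[j] <- log2(20) - H
    heights[, j] <- p * ic[j]
  }
  list(ic = ic, heights = heights)
}

#' Consensus motif pattern with alternation groups
#'
#' Summarizes cross-homolog variation at the given anchor positions: a
#' column whose top letter reaches \code{major} frequency is written as that
#' letter; otherwise, if the top two letters jointly reach \code{major},
#' the column becomes an alternation group like \code{"(N/D)"}; otherwise
#' \code{X}.
#'
#' @param msa character matrix from [starMsa()].
#' @param positions anchor positions (columns) of the motif.
#' @param major majority-frequency threshold (default 0.8).
#' @return a single pattern string.
#' @export
motifConsensus <- function(msa, positions, major = 0.8) {
  out <- vapply(positions, function(j) {
    col <- msa[, j]
    col <- col[col %in% .AA20]
    if (!length(col)) return("X")
    f <- sort(table(col), decreasing = TRUE) / length(col)
    if (f[1] >= major) return(names(f)[1])
    if (length(f) >= 2 && f[1] + f[2] >= major)
      return(sprintf("(%s/%s)", names(f)[1], names(f)[2]))
    "X"
  }, character(1))
  paste(out, collapse = "")
}

#' Write a logo matrix as TSV
#'
#' Position x letter heights, consumable by standard logo plotters.
#'
#' @param conservation result of [columnConservation()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLogoTsv <- function(conservation, path) {
  df <- data.frame(position = seq_along(conservation$ic),
                   ic = conservation$ic,
                   t(conservation$heights), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
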