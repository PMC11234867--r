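#' @import methods
NULL

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Scoring scheme for local protein alignment and E-value statistics
#'
#' Bundles a symmetric substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters \eqn{\lambda} (nats per score unit) and
#' \eqn{K} used to convert raw alignment scores into E-values
#' \eqn{E = K m n e^{-\lambda S}}.
#'
#' @slot matrix symmetric integer substitution matrix over the 20 canonical
#'   amino acids plus \code{X} (which scores 0 against everything).
#' @slot gapOpen positive gap-opening penalty; a gap of length \eqn{g} costs
#'   \code{gapOpen + g * gapExtend}.
#' @slot gapExtend positive per-residue gap-extension penalty.
#' @slot lambda Karlin-Altschul scale parameter (> 0).
#' @slot K Karlin-Altschul search-space constant (> 0).
#' @slot name label of the substitution matrix.
#'
#' @seealso [defaultScheme()]
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(matrix = "matrix", gapOpen = "integer", gapExtend = "integer",
                 lambda = "numeric", K = "numeric", name = "character"))

setValidity("ScoringScheme", function(object) {
  msg <- character()
  m <- object@matrix
  if (!is.numeric(m) || nrow(m) != ncol(m))
    msg <- c(msg, "matrix must be square and numeric")
  if (!identical(rownames(m), colnames(m)))
    msg <- c(msg, "matrix dimnames must agree")
  if (nrow(m) > 0 && max(abs(m - t(m))) > 0)
    msg <- c(msg, "matrix must be symmetric")
  if (object@gapOpen <= 0L || object@gapExtend <= 0L)
    msg <- c(msg, "gap penalties must be positive")
  if (object@gapExtend > object@gapOpen)
    msg <- c(msg, "gapExtend must not exceed gapOpen")
  if (object@lambda <= 0 || object@K <= 0)
    msg <- c(msg, "lambda and K must be positive")
  if (length(msg)) msg else TRUE
})

#' Pairwise local alignment hit
#'
#' One optimal Smith-Waterman local alignment between a query and a subject
#' protein, with Karlin-Altschul statistics. Ranges are 1-based inclusive
#' positions on the unaligned sequences; \code{pairs} holds the aligned
#' (query, subject) position pairs, strictly increasing in both columns.
#'
#' @slot queryId,subjectId sequence identifiers.
#' @slot rawScore optimal local alignment score (>= 0).
#' @slot bitScore normalized score \eqn{(\lambda S - \ln K)/\ln 2}.
#' @slot eValue expected number of chance hits at this score.
#' @slot identity fraction of identical positions over the alignment length
#'   (gaps included in the denominator), in [0, 1].
#' @slot qStart,qEnd,sStart,sEnd 1-based inclusive aligned ranges.
#' @slot pairs two-column integer matrix of aligned positions.
#'
#' @exportClass AlignmentHit
setClass("AlignmentHit",
  representation(queryId = "character", subjectId = "character",
                 rawScore = "integer", bitScore = "numeric", eValue = "numeric",
                 identity = "numeric", qStart = "integer", qEnd = "integer",
                 sStart = "integer", sEnd = "integer", pairs = "matrix"))

setValidity("AlignmentHit", function(object) {
  msg <- character()
  if (object@rawScore < 0L) msg <- c(msg, "rawScore must be >= 0")
  if (object@identity < 0 || object@identity > 1)
    msg <- c(msg, "identity must be in [0, 1]")
  p <- object@pairs
  if (nrow(p) > 1 && (any(diff(p[, 1]) <= 0) || any(diff(p[, 2]) <= 0)))
    msg <- c(msg, "aligned pairs must be strictly increasing in both columns")
  if (length(msg)) msg else TRUE
})

#' Ordered gene table of an annotated genome
#'
#' Holds one row per protein-coding gene (CDS) with 0-based half-open
#' coordinates, strand, product annotation, translated protein sequence and
#' the gene's rank (0-based position among the CDS of its contig ordered by
#' start). Gene-count windowing around anchor genes operates on ranks.
#' Contig nucleotide sequences are kept when the source provides them, so
#' the annotation can be re-serialized.
#'
#' @slot genomeId genome identifier.
#' @slot genes data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{start}, \code{end}, \code{strand}, \code{product},
#'   \code{protein_seq}, \code{rank}.
#' @slot sequences \code{DNAStringSet} of contig sequences (possibly empty).
#'
#' @seealso [parseGenBank()], [parseGffFasta()]
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
  representation(genomeId = "character", genes = "data.frame",
                 sequences = "ANY"))

.GENE_COLS <- c("gene_id", "contig_id", "start", "end", "strand",
                "product", "protein_seq", "rank")

setValidity("GenomeAnnotation", function(object) {
  g <- object@genes
  msg <- character()
  if (!all(.GENE_COLS %in% names(g)))
    return(paste("genes must have columns:", paste(.GENE_COLS, collapse = ", ")))
  if (nrow(g)) {
    if (any(g$start >= g$end)) msg <- c(msg, "start must be < end")
    if (!all(g$strand %in% c("+", "-"))) msg <- c(msg, "strand must be + or -")
    if (anyDuplicated(g$gene_id)) msg <- c(msg, "gene_id must be unique")
    bad <- grepl(sprintf("[^%sX]", paste(.AA20, collapse = "")), g$protein_seq)
    if (any(bad)) msg <- c(msg, "protein_seq may contain only the 20 canonical letters plus X")
    for (ct in unique(g$contig_id)) {
      sub <- g[g$contig_id == ct, ]
      sub <- sub[order(sub$start), ]
      if (!identical(as.integer(sub$rank), seq_len(nrow(sub)) - 1L))
        msg <- c(msg, sprintf("ranks on contig %s must be 0..n-1 in start order", ct))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Calpha structure model
#'
#' An ordered protein backbone trace: one Calpha coordinate per residue, with
#' one-letter residue codes and optional per-residue confidence (pLDDT-style,
#' 0-100, as stored in the B-factor column of predicted-model files).
#'
#' @slot modelId model identifier.
#' @slot resIndex strictly increasing residue numbers.
#' @slot aa one-letter residue codes.
#' @slot coords n x 3 matrix of Calpha coordinates in Angstrom.
#' @slot confidence per-residue confidence in [0, 100], or length 0 if absent.
#'
#' @seealso [parseStructure()], [makeHelicalBundle()]
#' @exportClass StructureModel
setClass("StructureModel",
  representation(modelId = "character", resIndex = "integer", aa = "character",
                 coords = "matrix", confidence = "numeric"))

setValidity("StructureModel", function(object) {
  n <- length(object@resIndex)
  msg <- character()
  if (n > 1 && any(diff(object@resIndex) <= 0))
    msg <- c(msg, "resIndex must be strictly increasing")
  if (nrow(object@coords) != n || ncol(object@coords) != 3)
    msg <- c(msg, "coords must be an n x 3 matrix")
  if (length(object@aa) != n) msg <- c(msg, "aa must have one letter per residue")
  if (n && !all(is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
  if (length(object@confidence) && length(object@confidence) != n)
    msg <- c(msg, "confidence must be empty or one value per residue")
  if (length(object@confidence) &&
      any(object@confidence < 0 | object@confidence > 100, na.rm = TRUE))
    msg <- c(msg, "confidence must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' Rigid-body superposition of two structure models
#'
#' The result of structure alignment: a proper rotation and translation
#' mapping the mobile model onto the reference, the aligned residue pairs
#' (row indices into the two models), the least-squares RMSD over those
#' pairs, and the TM-score normalized by \code{lNorm} residues.
#'
#' @slot rotation 3 x 3 proper rotation matrix (det +1).
#' @slot translation length-3 translation vector (Angstrom).
#' @slot pairs two-column integer matrix of aligned residue row indices
#'   (mobile, reference).
#' @slot rmsd root-mean-square deviation over the aligned pairs (Angstrom).
#' @slot tmScore TM-score in (0, 1].
#' @slot lNorm normalization length of the TM-score.
#'
#' @seealso [structureAlign()], [kabsch()], [tmScore()]
#' @exportClass Superposition
setClass("Superposition",
  representation(rotation = "matrix", translation = "numeric", pairs = "matrix",
                 rmsd = "numeric", tmScore = "numeric", lNorm = "integer"))

setValidity("Superposition", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3, 3))) msg <- c(msg, "rotation must be 3 x 3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-6)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (length(object@translation) != 3) msg <- c(msg, "translation must be length 3")
  if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
  if (object@tmScore <= 0 || object@tmScore > 1)
    msg <- c(msg, "tmScore must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Partition of candidates into types
#'
#' Connected components of the candidate similarity graph whose edges join
#' pairs with pairwise E-value below the threshold. Clusters are labelled
#' \code{type-1}, \code{type-2}, ... in order of decreasing size, ties broken
#' by the lexicographically smallest member.
#'
#' @slot clusters named list of character vectors of candidate ids.
#' @slot threshold the E-value threshold that defined the edges.
#'
#' @seealso [clusterTypes()]
#' @exportClass TypePartition
setClass("TypePartition",
  representation(clusters = "list", threshold = "numeric"))

setValidity("TypePartition", function(object) {
  ids <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(ids)) "clusters must be disjoint" else TRUE
})

#' Candidate report of a mining run
#'
#' Per-candidate provenance through every filter of the mining workflow
#' (anchor, window offset, structure screen, known-TPS exclusion), the type
#' assignment, active-site proximity motifs, and per-stage survivor counts.
#'
#' @slot candidates data.frame, one row per reported candidate.
#' @slot stageCounts named integer vector of survivors after each filter
#'   (window, hypothetical, structure, known_tps).
#' @slot typing [TypePartition-class] over the reported candidates.
#' @slot motifs named list (by gene id) of motif tables.
#' @slot superpositions named list (by gene id) of the best-reference
#'   [Superposition-class].
#' @slot config the configuration list the run used.
#'
#' @seealso [runMining()]
#' @exportClass CandidateReport
setClass("CandidateReport",
  representation(candidates = "data.frame", stageCounts = "integer",
                 typing = "TypePartition", motifs = "list",
                 superpositions = "list", config = "list"))

setValidity("CandidateReport", function(object) {
  sc <- object@stageCounts
  if (length(sc) && any(diff(sc) > 0L))
    "stage counts must be non-increasing along the filter chain" else TRUE
})
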