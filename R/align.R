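#' @include scoring.R
NULL

# validate a protein string against the scheme alphabet
.check_protein <- function(x, what = "sequence", alphabet = c(.AA20, "X")) {
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a nonempty protein string")
  bad <- setdiff(strsplit(x, "")[[1]], alphabet)
  if (length(bad))
    stop(what, " contains letters outside the scheme alphabet: ",
         paste(unique(bad), collapse = ""))
  invisible(x)
}

# one pairwiseAlignment call shared by the exported wrappers
.pairwise_local <- function(patterns, subject, scheme) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = Biostrings::AAString(subject),
    type = "local",
    substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gapOpen,
    gapExtension = scheme@gapExtend)
}

#' Optimal Smith-Waterman local alignment of two proteins
#'
#' Computes the optimal local alignment under affine gap penalties (a gap of
#' length g costs \code{gapOpen + g * gapExtend}) and attaches
#' Karlin-Altschul statistics computed with m, n equal to the two sequence
#' lengths. \code{X} is score-neutral. The result is deterministic for fixed
#' inputs; when several alignments share the optimal score one of them is
#' returned.
#'
#' @param a,b query and subject protein sequences (characters over the 20
#'   canonical letters plus X).
#' @param scheme a [ScoringScheme-class].
#' @param queryId,subjectId identifiers recorded in the hit.
#' @return an [AlignmentHit-class].
#' @examples
#' hit <- smithWaterman("HEAGAWGHEE", "PAWHEAE")
#' rawScore(hit)
#' @export
smithWaterman <- function(a, b, scheme = defaultScheme(),
                          queryId = "query", subjectId = "subject") {
  .check_protein(a, "query", rownames(scheme@matrix))
  .check_protein(b, "subject", rownames(scheme@matrix))
  pa <- .pairwise_local(a, b, scheme)
  s <- max(0L, as.integer(round(Biostrings::score(pa))))

  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  qpos <- IRanges::start(Biostrings::pattern(pa))
  spos <- IRanges::start(Biostrings::subject(pa))
  qi <- si <- integer(0)
  nid <- 0L
  q <- qpos; p <- spos
  for (k in seq_along(ap)) {
    if (ap[k] != "-" && as_[k] != "-") {
      qi <- c(qi, q); si <- c(si, p)
      if (ap[k] == as_[k]) nid <- nid + 1L
    }
    if (ap[k] != "-") q <- q + 1L
    if (as_[k] != "-") p <- p + 1L
  }
  pairs <- cbind(i = qi, j = si)
  alen <- length(ap)
  new("AlignmentHit",
      queryId = queryId, subjectId = subjectId, rawScore = s,
      bitScore = bitScore(s, scheme),
      eValue = eValue(s, nchar(a), nchar(b), scheme),
      identity = if (alen) nid / alen else 0,
      qStart = as.integer(qpos), qEnd = as.integer(IRanges::end(Biostrings::pattern(pa))),
      sStart = as.integer(spos), sEnd = as.integer(IRanges::end(Biostrings::subject(pa))),
      pairs = pairs)
}

#' Search a protein database with one query
#'
#' Aligns the query against every database sequence and reports hits with
#' E-value below \code{eMax}. The database size n in the E-value formula is
#' the total residue count of the database, as in BLAST. Hits are sorted by
#' ascending E-value, ties broken by subject id; only hits with positive raw
#' score are reported.
#'
#' @param query protein sequence.
#' @param db named character vector of protein sequences (the names are the
#'   subject ids), or an \code{AAStringSet}.
#' @param scheme a [ScoringScheme-class].
#' @param eMax E-value cutoff (hits must be strictly below it).
#' @param queryId identifier recorded in the hit table.
#' @return a data.frame with BLAST-tabular-style columns \code{qseqid},
#'   \code{sseqid}, \code{pident}, \code{length}, \code{qstart}, \code{qend},
#'   \code{sstart}, \code{send}, \code{evalue}, \code{bitscore},
#'   \code{rawscore} (coordinates 1-based inclusive).
#' @export
searchHomologs <- function(query, db, scheme = defaultScheme(), eMax = Inf,
                           queryId = "query") {
  if (methods::is(db, "XStringSet")) db <- stats::setNames(as.character(db), names(db))
  stopifnot(length(db) >= 1L)
  if (is.null(names(db)) || any(!nzchar(names(db))))
    stop("db sequences must be named")
  .check_protein(query, "query", rownames(scheme@matrix))

  pa <- .pairwise_local(db, query, scheme)
  sc <- pmax(0L, as.integer(round(Biostrings::score(pa))))
  ntotal <- sum(nchar(db))
  ev <- eValue(sc, nchar(query), ntotal, scheme)
  alen <- nchar(as.character(Biostrings::alignedPattern(pa)))
  nid <- Biostrings::nmatch(pa)

  hits <- data.frame(
    qseqid = queryId,
    sseqid = names(db),
    pident = round(100 * nid / pmax(alen, 1L), 2),
    length = alen,
    qstart = IRanges::start(Biostrings::subject(pa)),
    qend = IRanges::end(Biostrings::subject(pa)),
    sstart = IRanges::start(Biostrings::pattern(pa)),
    send = IRanges::end(Biostrings::pattern(pa)),
    evalue = ev,
    bitscore = bitScore(sc, scheme),
    rawscore = sc,
    stringsAsFactors = FALSE)
  hits <- hits[hits$rawscore > 0L & hits$evalue < eMax, , drop = FALSE]
  hits <- hits[order(hits$evalue, hits$sseqid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Exclude candidates resembling known TPS sequences
#'
#' Drops every candidate whose best hit against the known-TPS database has
#' E-value below \code{eMax}; candidates with no positive-scoring hit are
#' retained. Input order is preserved. Excluded ids and their best hits are
#' reported via \code{message()} and attached as the \code{"excluded"}
#' attribute; the best known-TPS E-value of every candidate is attached as
#' the \code{"audit"} attribute.
#'
#' @param candidates named character vector of candidate protein sequences.
#' @param knownTpsDb named character vector (or \code{AAStringSet}) of known
#'   TPS protein sequences.
#' @param scheme a [ScoringScheme-class].
#' @param eMax exclusion E-value cutoff.
#' @return the retained subset of \code{candidates}.
#' @export
excludeKnownTps <- function(candidates, knownTpsDb, scheme = defaultScheme(),
                            eMax = 1e-5) {
  if (methods::is(knownTpsDb, "XStringSet"))
    knownTpsDb <- stats::setNames(as.character(knownTpsDb), names(knownTpsDb))
  stopifnot(length(knownTpsDb) >= 1L)
  if (!length(candidates)) {
    out <- candidates
    attr(out, "excluded") <- data.frame(id = character(), best_subject = character(),
                                        evalue = numeric())
    attr(out, "audit") <- stats::setNames(numeric(0), character(0))
    return(out)
  }
  best <- lapply(seq_along(candidates), function(i) {
    h <- searchHomologs(candidates[[i]], knownTpsDb, scheme, eMax = Inf,
                        queryId = names(candidates)[i])
    if (nrow(h)) h[1, c("sseqid", "evalue")] else
      data.frame(sseqid = NA_character_, evalue = Inf)
  })
  bestEv <- vapply(best, function(x) x$evalue, numeric(1))
  bestId <- vapply(best, function(x) as.character(x$sseqid), character(1))
  drop <- bestEv < eMax
  for (i in which(drop))
    message(sprintf("excluding %s: best known-TPS hit %s at E = %.3g",
                    names(candidates)[i], bestId[i], bestEv[i]))
  out <- candidates[!drop]
  attr(out, "excluded") <- data.frame(id = names(candidates)[drop],
                                      best_subject = bestId[drop],
                                      evalue = bestEv[drop],
                                      stringsAsFactors = FALSE)
  attr(out, "audit") <- stats::setNames(bestEv, names(candidates))
  out
}

#' Write a hit table as TSV
#'
#' @param hits a hit data.frame as returned by [searchHomologs()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeHitsTsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
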