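#' @include AllClasses.R
NULL

#' Accessors for tpsmine S4 objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @return the slot value described for each method.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))
#' @rdname accessors
#' @export
setGeneric("geneTable", function(object) standardGeneric("geneTable"))
#' @rdname accessors
#' @export
setGeneric("contigSeqs", function(object) standardGeneric("contigSeqs"))
#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setGeneric("caCoords", function(object) standardGeneric("caCoords"))
#' @rdname accessors
#' @export
setGeneric("residueIndices", function(object) standardGeneric("residueIndices"))
#' @rdname accessors
#' @export
setGeneric("residueLetters", function(object) standardGeneric("residueLetters"))
#' @rdname accessors
#' @export
setGeneric("confidences", function(object) standardGeneric("confidences"))
#' @rdname accessors
#' @export
setGeneric("nResidues", function(object) standardGeneric("nResidues"))
#' @rdname accessors
#' @export
setGeneric("alignedPairs", function(object) standardGeneric("alignedPairs"))
#' @rdname accessors
#' @export
setGeneric("rawScore", function(object) standardGeneric("rawScore"))
#' @rdname accessors
#' @export
setGeneric("eValueOf", function(object) standardGeneric("eValueOf"))
#' @rdname accessors
#' @export
setGeneric("identityFraction", function(object) standardGeneric("identityFraction"))
#' @rdname accessors
#' @export
setGeneric("rotationMatrix", function(object) standardGeneric("rotationMatrix"))
#' @rdname accessors
#' @export
setGeneric("translationVector", function(object) standardGeneric("translationVector"))
#' @rdname accessors
#' @export
setGeneric("rmsdOf", function(object) standardGeneric("rmsdOf"))
#' @rdname accessors
#' @export
setGeneric("tmScoreOf", function(object) standardGeneric("tmScoreOf"))
#' @rdname accessors
#' @export
setGeneric("typeClusters", function(object) standardGeneric("typeClusters"))
#' @rdname accessors
#' @export
setGeneric("candidateTable", function(object) standardGeneric("candidateTable"))
#' @rdname accessors
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))
#' @rdname accessors
#' @export
setGeneric("motifTables", function(object) standardGeneric("motifTables"))

#' @rdname accessors
setMethod("genomeId", "GenomeAnnotation", function(object) object@genomeId)
#' @rdname accessors
setMethod("geneTable", "GenomeAnnotation", function(object) object@genes)
#' @rdname accessors
setMethod("contigSeqs", "GenomeAnnotation", function(object) object@sequences)

#' @rdname accessors
setMethod("modelId", "StructureModel", function(object) object@modelId)
#' @rdname accessors
setMethod("caCoords", "StructureModel", function(object) object@coords)
#' @rdname accessors
setMethod("residueIndices", "StructureModel", function(object) object@resIndex)
#' @rdname accessors
setMethod("residueLetters", "StructureModel", function(object) object@aa)
#' @rdname accessors
setMethod("confidences", "StructureModel", function(object) object@confidence)
#' @rdname accessors
setMethod("nResidues", "StructureModel", function(object) length(object@resIndex))

#' @rdname accessors
setMethod("alignedPairs", "AlignmentHit", function(object) object@pairs)
#' @rdname accessors
setMethod("rawScore", "AlignmentHit", function(object) object@rawScore)
#' @rdname accessors
setMethod("eValueOf", "AlignmentHit", function(object) object@eValue)
#' @rdname accessors
setMethod("identityFraction", "AlignmentHit", function(object) object@identity)

#' @rdname accessors
setMethod("alignedPairs", "Superposition", function(object) object@pairs)
#' @rdname accessors
setMethod("rotationMatrix", "Superposition", function(object) object@rotation)
#' @rdname accessors
setMethod("translationVector", "Superposition", function(object) object@translation)
#' @rdname accessors
setMethod("rmsdOf", "Superposition", function(object) object@rmsd)
#' @rdname accessors
setMethod("tmScoreOf", "Superposition", function(object) object@tmScore)

#' @rdname accessors
setMethod("typeClusters", "TypePartition", function(object) object@clusters)

#' @rdname accessors
setMethod("candidateTable", "CandidateReport", function(object) object@candidates)
#' @rdname accessors
setMethod("stageCounts", "CandidateReport", function(object) object@stageCounts)
#' @rdname accessors
setMethod("motifTables", "CandidateReport", function(object) object@motifs)
#' @rdname accessors
setMethod("typeClusters", "CandidateReport", function(object) object@typing@clusters)

setMethod("show", "GenomeAnnotation", function(object) {
  g <- object@genes
  cat("GenomeAnnotation:", object@genomeId, "\n")
  cat(" ", nrow(g), "CDS on", length(unique(g$contig_id)), "contig(s)\n")
  if (nrow(g)) {
    hyp <- sum(g$product == "" | grepl("hypothetical", g$product, ignore.case = TRUE))
    cat(" ", hyp, "annotated as hypothetical/empty\n")
  }
})

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel:", object@modelId, "-", nResidues(object), "residues\n")
  if (length(object@confidence))
    cat("  mean confidence:", round(mean(object@confidence), 1), "\n")
})

setMethod("show", "AlignmentHit", function(object) {
  cat(sprintf("AlignmentHit %s vs %s: score %d, bits %.1f, E %.3g, id %.1f%%\n",
              object@queryId, object@subjectId, object@rawScore,
              object@bitScore, object@eValue, 100 * object@identity))
})

setMethod("show", "Superposition", function(object) {
  cat(sprintf("Superposition: %d aligned pairs, RMSD %.2f A, TM-score %.3f (L=%d)\n",
              nrow(object@pairs), object@rmsd, object@tmScore, object@lNorm))
})

setMethod("show", "TypePartition", function(object) {
  cl <- object@clusters
  cat("TypePartition:", length(cl), "type(s) at E <", object@threshold, "\n")
  for (nm in names(cl))
    cat(" ", nm, ":", paste(cl[[nm]], collapse = ", "), "\n")
})

setMethod("show", "CandidateReport", function(object) {
  cat("CandidateReport:", nrow(object@candidates), "candidate(s)\n")
  cat("  stage counts:",
      paste(names(object@stageCounts), object@stageCounts,
            sep = "=", collapse = " -> "), "\n")
  cat(" ", length(object@typing@clusters), "type(s)\n")
})
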