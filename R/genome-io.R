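#' @include AllClasses.R
NULL

#' Translate a coding sequence
#'
#' Translates a nucleotide CDS using the requested genetic code (default:
#' table 11, bacterial). A trailing partial codon is trimmed. Alternative
#' initiator codons at position 0 translate to M. Ambiguous IUPAC codons that
#' resolve to a unique amino acid are translated; unresolvable codons give X.
#' Translation stops at (and does not include) the first stop codon.
#'
#' @param ntSeq nucleotide string (IUPAC letters).
#' @param tableId NCBI genetic-code table id (default 11).
#' @return amino-acid string over the 20 canonical letters plus X.
#' @examples
#' translateCds("ATGGCAACC")        # "MAT"
#' translateCds("GTGGCA")           # "MA" (GTG initiator under table 11)
#' @export
translateCds <- function(ntSeq, tableId = 11L) {
  ntSeq <- toupper(gsub("\\s", "", ntSeq))
  ntSeq <- substr(ntSeq, 1L, 3L * (nchar(ntSeq) %/% 3L))
  if (!nchar(ntSeq)) return("")
  dna <- Biostrings::DNAString(ntSeq)  # errors on non-IUPAC characters
  code <- Biostrings::getGeneticCode(as.character(tableId))
  aa <- as.character(Biostrings::translate(dna, genetic.code = code,
                                           if.fuzzy.codon = "solve"))
  aa <- sub("\\*.*$", "", aa)           # stop codons not included
  gsub("[^A-Z]|[BJOUZ]", "X", aa)       # anything non-canonical becomes X
}

# ---- internal helpers -------------------------------------------------------

# assemble a GenomeAnnotation from a raw gene list, assigning ranks per contig
.build_annotation <- function(genomeId, genes, sequences = NULL) {
  if (is.null(sequences)) sequences <- Biostrings::DNAStringSet()
  if (!nrow(genes)) {
    genes <- data.frame(gene_id = character(), contig_id = character(),
                        start = integer(), end = integer(), strand = character(),
                        product = character(), protein_seq = character(),
                        rank = integer(), stringsAsFactors = FALSE)
    return(new("GenomeAnnotation", genomeId = genomeId, genes = genes,
               sequences = sequences))
  }
  genes <- genes[order(genes$contig_id, genes$start), , drop = FALSE]
  genes$rank <- as.integer(stats::ave(genes$start, genes$contig_id,
                                      FUN = function(x) seq_along(x) - 1L))
  rownames(genes) <- NULL
  new("GenomeAnnotation", genomeId = genomeId, genes = genes,
      sequences = sequences)
}

# parse a GenBank location string into strand + 1-based inclusive parts.
# Returns NULL (skip) for locations that reference other records.
.parse_gb_location <- function(loc, where = "") {
  loc <- gsub("\\s", "", loc)
  if (grepl(":", loc, fixed = TRUE)) return(NULL)   # trans-record join
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  if (grepl("^join\\(|^order\\(", loc)) {
    loc <- sub("^(join|order)\\(", "", loc)
    loc <- sub("\\)$", "", loc)
  }
  if (grepl("complement", loc)) {  # mixed-strand join: unsupported
    return(NULL)
  }
  if (grepl("[<>]", loc)) {
    warning("fuzzy coordinates truncated in ", where, ": ", loc)
    loc <- gsub("[<>]", "", loc)
  }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  out <- matrix(NA_integer_, length(parts), 2)
  for (k in seq_along(parts)) {
    p <- strsplit(parts[k], "..", fixed = TRUE)[[1]]
    if (length(p) == 1L) p <- c(p, p)   # single-base location
    s <- suppressWarnings(as.integer(p[1])); e <- suppressWarnings(as.integer(p[2]))
    if (is.na(s) || is.na(e) || s > e) return(NULL)
    out[k, ] <- c(s, e)
  }
  list(strand = strand, parts = out)
}

# extract and splice a CDS nucleotide sequence from a contig
.splice_cds <- function(contigSeq, parts, strand) {
  segs <- vapply(seq_len(nrow(parts)), function(k)
    as.character(Biostrings::subseq(contigSeq, parts[k, 1], parts[k, 2])),
    character(1))
  nt <- paste(segs, collapse = "")
  if (strand == "-")
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  nt
}

# ---- GenBank ----------------------------------------------------------------

#' Read an annotated genome from a GenBank flat file
#'
#' Parses every CDS feature of every record into one gene row. The protein
#' sequence is taken from the \code{/translation} qualifier when present and
#' otherwise computed with [translateCds()] on the spliced nucleotide span
#' (honouring \code{/codon_start}). Coordinates are stored 0-based half-open;
#' gene ranks are assigned per contig by start coordinate. CDS features with
#' unresolvable locations (e.g. joins across records) are skipped with a
#' warning rather than aborting the parse.
#'
#' @param path GenBank flat file.
#' @param genomeId genome identifier; defaults to the file name without
#'   extension.
#' @param tableId genetic-code table for translation (default 11).
#' @return a [GenomeAnnotation-class].
#' @export
parseGenBank <- function(path, genomeId = NULL, tableId = 11L) {
  if (!file.exists(path)) stop("cannot read GenBank file: ", path)
  if (is.null(genomeId))
    genomeId <- sub("\\.(gb|gbk|gbff|genbank)$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(grepl("^LOCUS", lines)))
    stop("parse error at line 1: not a GenBank flat file: ", path)

  recStarts <- grep("^LOCUS", lines)
  recEnds <- c(recStarts[-1] - 1L, length(lines))
  allGenes <- list()
  seqs <- character(); seqNames <- character()
  autoId <- 0L

  for (r in seq_along(recStarts)) {
    rec <- lines[recStarts[r]:recEnds[r]]
    contig <- strsplit(trimws(rec[1]), "\\s+")[[1]][2]
    if (is.na(contig)) stop("parse error at line ", recStarts[r],
                            ": LOCUS line lacks a name")
    featStart <- grep("^FEATURES", rec)
    originAt <- grep("^ORIGIN", rec)
    contigSeq <- NULL
    if (length(originAt)) {
      endAt <- grep("^//", rec)
      endAt <- if (length(endAt)) endAt[endAt > originAt[1]][1] else length(rec) + 1L
      if (is.na(endAt)) endAt <- length(rec) + 1L
      seqLines <- if (endAt - 1L >= originAt[1] + 1L)
        rec[(originAt[1] + 1L):(endAt - 1L)] else character(0)
      nt <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
      if (nzchar(nt)) {
        contigSeq <- Biostrings::DNAString(nt)
        seqs <- c(seqs, nt); seqNames <- c(seqNames, contig)
      }
    }
    if (!length(featStart)) next
    featEnd <- if (length(originAt)) originAt[1] - 1L else length(rec)
    feat <- rec[(featStart[1] + 1L):featEnd]

    # split the feature table into individual features
    keyAt <- grep("^ {5}\\S", feat)
    if (!length(keyAt)) next
    keyEnd <- c(keyAt[-1] - 1L, length(feat))
    for (f in seq_along(keyAt)) {
      key <- trimws(substr(feat[keyAt[f]], 1, 21))
      if (key != "CDS") next
      block <- feat[keyAt[f]:keyEnd[f]]
      # location: first line remainder plus continuation lines (no "/")
      locLines <- sub("^ {5}\\S+\\s*", "", block[1])
      k <- 2L
      while (k <= length(block) && !grepl("^\\s*/", block[k])) {
        locLines <- paste0(locLines, trimws(block[k])); k <- k + 1L
      }
      qualText <- if (k <= length(block))
        paste(trimws(block[k:length(block)]), collapse = "\n") else ""
      quals <- .parse_gb_qualifiers(qualText)

      locusLine <- recStarts[r] + featStart[1] + keyAt[f] - 1L
      loc <- .parse_gb_location(locLines,
                                sprintf("%s line %d", basename(path), locusLine))
      if (is.null(loc)) {
        warning(sprintf("skipping CDS with unresolvable location at %s line %d",
                        basename(path), locusLine))
        next
      }
      geneId <- quals[["locus_tag"]] %||% quals[["protein_id"]] %||% {
        autoId <- autoId + 1L
        sprintf("%s_cds%03d", contig, autoId)
      }
      prot <- quals[["translation"]]
      if (is.null(prot)) {
        if (is.null(contigSeq)) {
          prot <- ""
        } else {
          nt <- .splice_cds(contigSeq, loc$parts, loc$strand)
          cs <- suppressWarnings(as.integer(quals[["codon_start"]] %||% "1"))
          if (!is.na(cs) && cs > 1L) nt <- substr(nt, cs, nchar(nt))
          prot <- translateCds(nt, tableId)
        }
      } else {
        prot <- gsub("\\s", "", prot)
      }
      allGenes[[length(allGenes) + 1L]] <- data.frame(
        gene_id = geneId, contig_id = contig,
        start = min(loc$parts[, 1]) - 1L, end = max(loc$parts[, 2]),
        strand = loc$strand, product = quals[["product"]] %||% "",
        protein_seq = prot, rank = 0L, stringsAsFactors = FALSE)
    }
  }
  genes <- if (length(allGenes)) do.call(rbind, allGenes) else
    data.frame(gene_id = character(), contig_id = character(), start = integer(),
               end = integer(), strand = character(), product = character(),
               protein_seq = character(), rank = integer())
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- seqNames
  .build_annotation(genomeId, genes, dna)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse "/key=value" qualifiers, with multi-line values and quoted strings
.parse_gb_qualifiers <- function(text) {
  if (!nzchar(text)) return(list())
  lines <- strsplit(text, "\n")[[1]]
  starts <- grep("^/", lines)
  out <- list()
  if (!length(starts)) return(out)
  ends <- c(starts[-1] - 1L, length(lines))
  for (i in seq_along(starts)) {
    chunk <- paste(lines[starts[i]:ends[i]], collapse = "")
    m <- regmatches(chunk, regexec("^/([A-Za-z_]+)(=(.*))?$", chunk))[[1]]
    if (length(m) < 2) next
    key <- m[2]
    val <- if (length(m) >= 4) m[4] else ""
    val <- gsub('^"|"$', "", val)
    out[[key]] <- val
  }
  out
}

# ---- GFF3 + FASTA -----------------------------------------------------------

#' Read an annotated genome from GFF3 plus genome FASTA
#'
#' Same contract as [parseGenBank()]: one gene row per CDS group. CDS lines
#' sharing a \code{Parent} are spliced into a single gene; translations are
#' computed from the genome sequence (reverse-complemented for minus-strand
#' genes, honouring the phase of the 5'-most segment). GFF3 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param gffPath GFF3 annotation file.
#' @param fastaPath genome FASTA; every CDS seqid must be present.
#' @param genomeId genome identifier; defaults to the GFF file name.
#' @param tableId genetic-code table (default 11).
#' @return a [GenomeAnnotation-class].
#' @export
parseGffFasta <- function(gffPath, fastaPath, genomeId = NULL, tableId = 11L) {
  if (is.null(genomeId)) genomeId <- sub("\\.gff3?$", "", basename(gffPath))
  genome <- Biostrings::readDNAStringSet(fastaPath)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gffPath)
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  if (!length(gr)) return(.build_annotation(genomeId, data.frame(), genome))

  seqids <- as.character(GenomicRanges::seqnames(gr))
  missing <- setdiff(unique(seqids), names(genome))
  if (length(missing))
    stop("seqid(s) missing from FASTA: ", paste(missing, collapse = ", "))

  parent <- if (!is.null(gr$Parent)) {
    vapply(as.list(gr$Parent), function(p)
      if (length(p)) as.character(p[1]) else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  key <- ifelse(!is.na(parent), parent, ifelse(!is.na(id), id,
                paste0("cds", seq_along(gr))))

  rows <- lapply(split(seq_along(gr), key), function(idx) {
    sub <- gr[idx]
    sub <- sub[order(GenomicRanges::start(sub))]
    strand <- as.character(GenomicRanges::strand(sub))[1]
    if (strand == "*") strand <- "+"
    contig <- as.character(GenomicRanges::seqnames(sub))[1]
    parts <- cbind(GenomicRanges::start(sub), GenomicRanges::end(sub))
    nt <- .splice_cds(genome[[contig]], parts, strand)
    ph <- sub$phase
    phase <- 0L
    if (!is.null(ph)) {
      p5 <- if (strand == "+") ph[1] else ph[length(ph)]
      if (!is.na(p5)) phase <- as.integer(p5)
    }
    if (phase > 0L) nt <- substr(nt, phase + 1L, nchar(nt))
    prod <- if (!is.null(sub$product)) as.character(sub$product)[1] else NA_character_
    if (is.na(prod)) prod <- ""
    data.frame(gene_id = key[idx[1]], contig_id = contig,
               start = min(parts[, 1]) - 1L, end = max(parts[, 2]),
               strand = strand, product = prod,
               protein_seq = translateCds(nt, tableId),
               rank = 0L, stringsAsFactors = FALSE)
  })
  .build_annotation(genomeId, do.call(rbind, rows), genome)
}

# ---- writers ----------------------------------------------------------------

#' Serialize a genome annotation as GFF3 + FASTA
#'
#' Writes one CDS line per gene (1-based inclusive coordinates, phase 0,
#' \code{ID} and \code{product} attributes) and the contig sequences as
#' FASTA. Re-parsing with [parseGffFasta()] reproduces the gene table.
#'
#' @param annotation a [GenomeAnnotation-class] with contig sequences.
#' @param gffPath,fastaPath output paths.
#' @return the GFF path, invisibly.
#' @export
writeGenomeGff <- function(annotation, gffPath, fastaPath) {
  seqs <- contigSeqs(annotation)
  if (!length(seqs)) stop("annotation carries no contig sequences")
  g <- geneTable(annotation)
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig_id,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand)
  gr$type <- "CDS"
  gr$ID <- g$gene_id
  gr$product <- g$product
  gr$phase <- 0L
  rtracklayer::export(gr, gffPath, format = "gff3")
  Biostrings::writeXStringSet(seqs, fastaPath)
  invisible(gffPath)
}

#' Export all protein sequences of a genome as FASTA
#'
#' Headers follow \code{genomeId|contigId|geneId|rank}. Genes with empty
#' translations are skipped.
#'
#' @param annotation a [GenomeAnnotation-class].
#' @param path output FASTA path.
#' @return the path, invisibly.
#' @export
writeProteinFasta <- function(annotation, path) {
  g <- geneTable(annotation)
  g <- g[nzchar(g$protein_seq), , drop = FALSE]
  aa <- Biostrings::AAStringSet(g$protein_seq)
  names(aa) <- sprintf("%s|%s|%s|%d", genomeId(annotation), g$contig_id,
                       g$gene_id, g$rank)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
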