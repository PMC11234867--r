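#' @include neighborhood.R superpose.R typing.R motifs.R phylo.R
NULL

#' Mining run configuration
#'
#' Validates and assembles the configuration of a mining run. All thresholds
#' are the workflow defaults: a plus/minus 10-gene window around each E-IDS
#' anchor, anchor and known-TPS exclusion cutoffs of 1e-5, the TM >= 0.5
#' same-fold criterion, pLDDT trimming at 70, type clustering at E < 0.1,
#' homolog census at E < 1e-5, and a 5 Angstrom Calpha proximity cutoff for
#' active-site residues.
#'
#' @param genomes character vector of GenBank files, or a directory of
#'   \code{.gb}/\code{.gbk}/\code{.gbff} files.
#' @param structures directory of per-gene structure models, looked up as
#'   \code{<gene_id>.pdb} or \code{<gene_id>.cif}.
#' @param eidsFasta FASTA of E-IDS anchor reference proteins.
#' @param knownTpsFasta FASTA of known TPS proteins (exclusion set).
#' @param refStructures named character vector of reference TPS structure
#'   files (class I / IB / IC).
#' @param catalyticRefs optional named list of [catalyticReference()] tables,
#'   one per reference structure id; motifs are skipped when absent.
#' @param windowK window half-width in genes; \code{Inf} disables the window.
#' @param anchorEMax,knownTpsEMax,typeEMax,homologEMax E-value thresholds.
#' @param tmMin TM-score pass threshold.
#' @param plddtMin confidence trim threshold.
#' @param proximityCutoff active-site Calpha distance cutoff (Angstrom).
#' @param keywords hypothetical-product keywords.
#' @param scheme a [ScoringScheme-class].
#' @param seed seed recorded with the run.
#' @return a validated configuration list of class \code{MiningConfig}.
#' @export
miningConfig <- function(genomes, structures, eidsFasta, knownTpsFasta,
                         refStructures, catalyticRefs = NULL,
                         windowK = 10, anchorEMax = 1e-5, knownTpsEMax = 1e-5,
                         tmMin = 0.5, plddtMin = 70, typeEMax = 0.1,
                         homologEMax = 1e-5, proximityCutoff = 5.0,
                         keywords = .DEFAULT_HYPOTHETICAL_KEYWORDS,
                         scheme = defaultScheme(), seed = 1L) {
  if (length(genomes) == 1L && dir.exists(genomes))
    genomes <- list.files(genomes, "\\.(gb|gbk|gbff|genbank)$", full.names = TRUE)
  missing <- genomes[!file.exists(genomes)]
  for (p in c(eidsFasta, knownTpsFasta, refStructures))
    if (!file.exists(p)) missing <- c(missing, p)
  if (!dir.exists(structures)) missing <- c(missing, structures)
  if (length(missing))
    stop("config error: missing input path(s): ", paste(missing, collapse = ", "))
  thresholds <- c(windowK = windowK, anchorEMax = anchorEMax,
                  knownTpsEMax = knownTpsEMax, tmMin = tmMin,
                  plddtMin = plddtMin, typeEMax = typeEMax,
                  homologEMax = homologEMax, proximityCutoff = proximityCutoff)
  if (any(thresholds <= 0))
    stop("config error: all thresholds must be positive")
  cfg <- list(genomes = genomes, structures = structures,
              eidsFasta = eidsFasta, knownTpsFasta = knownTpsFasta,
              refStructures = refStructures, catalyticRefs = catalyticRefs,
              windowK = windowK, anchorEMax = anchorEMax,
              knownTpsEMax = knownTpsEMax, tmMin = tmMin, plddtMin = plddtMin,
              typeEMax = typeEMax, homologEMax = homologEMax,
              proximityCutoff = proximityCutoff, keywords = keywords,
              scheme = scheme, seed = as.integer(seed))
  class(cfg) <- "MiningConfig"
  cfg
}

# find the structure model file of a gene, or NA
.structure_path <- function(structDir, geneId) {
  for (ext in c(".pdb", ".cif", ".mmcif")) {
    p <- file.path(structDir, paste0(geneId, ext))
    if (file.exists(p)) return(p)
  }
  NA_character_
}

.empty_report_df <- function() {
  data.frame(genome_id = character(), contig_id = character(),
             gene_id = character(), offset = integer(),
             anchor_gene_id = character(), anchor_evalue = numeric(),
             product = character(), length = integer(),
             best_ref = character(), tm_score = numeric(), rmsd = numeric(),
             known_tps_evalue = numeric(), type = character(),
             motifs = character(), stringsAsFactors = FALSE)
}

#' Run the structural-model-based mining workflow
#'
#' Executes the four filters in order over every genome: (1) locate E-IDS
#' anchors and collect the genes within the window, deduplicated across
#' overlapping anchor windows by smallest absolute offset; (2) keep
#' hypothetical-annotated candidates; (3) align each candidate's trimmed
#' structure model against the reference TPS structures and keep those
#' reaching the TM-score threshold (candidates without a model file are
#' skipped with a log line, mirroring the restriction to proteins with
#' available models); (4) exclude candidates resembling known TPS
#' sequences. Survivors are clustered into types by pairwise E-value, and
#' active-site proximity motifs are extracted against each candidate's best
#' reference. Deterministic for a fixed configuration.
#'
#' @param config a [miningConfig()].
#' @param verbose emit one log line per candidate per filter.
#' @return a [CandidateReport-class].
#' @export
runMining <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "MiningConfig"))
  say <- if (verbose) message else function(...) invisible(NULL)
  scheme <- config$scheme
  eids <- Biostrings::readAAStringSet(config$eidsFasta)
  knownTps <- Biostrings::readAAStringSet(config$knownTpsFasta)
  refNames <- names(config$refStructures)
  refs <- lapply(config$refStructures, parseStructure)
  if (is.null(refNames)) refNames <- vapply(refs, modelId, character(1))
  names(refs) <- vapply(refs, modelId, character(1))

  windowed <- list()
  for (gb in config$genomes) {
    genome <- parseGenBank(gb)
    anchors <- findAnchors(genome, eids, scheme, config$anchorEMax)
    if (!nrow(anchors)) {
      say("no anchors in genome ", genomeId(genome))
      next
    }
    cand <- list()
    for (a in seq_len(nrow(anchors)))
      cand[[a]] <- extractWindow(genome, anchors[a, ], config$windowK)
    cand <- do.call(rbind, cand)
    if (!nrow(cand)) next
    # dedupe overlapping anchor windows: keep the smallest |offset|
    cand <- cand[order(abs(cand$offset)), , drop = FALSE]
    cand <- cand[!duplicated(cand$gene_id), , drop = FALSE]
    cand$genome_id <- genomeId(genome)
    windowed[[length(windowed) + 1L]] <- cand
  }
  windowed <- if (length(windowed)) do.call(rbind, windowed) else NULL
  if (is.null(windowed) || !nrow(windowed)) {
    say("no candidates in any window; empty report")
    return(new("CandidateReport", candidates = .empty_report_df(),
               stageCounts = c(window = 0L, hypothetical = 0L,
                               structure = 0L, known_tps = 0L),
               typing = new("TypePartition", clusters = list(),
                            threshold = config$typeEMax),
               motifs = list(), superpositions = list(),
               config = unclass(config)))
  }
  nWindow <- nrow(windowed)

  hyp <- filterHypothetical(windowed, config$keywords)
  nHyp <- nrow(hyp)
  for (i in seq_len(nHyp))
    say(sprintf("[window/hypothetical] %s offset %+d (anchor %s, E=%.2g)",
                hyp$gene_id[i], hyp$offset[i], hyp$anchor_gene_id[i],
                hyp$anchor_evalue[i]))

  # structure screen
  keep <- logical(nHyp)
  bestRef <- character(nHyp); bestTm <- numeric(nHyp); bestRmsd <- numeric(nHyp)
  sups <- list()
  models <- list()
  for (i in seq_len(nHyp)) {
    p <- .structure_path(config$structures, hyp$gene_id[i])
    if (is.na(p)) {
      say(sprintf("[structure] %s: no model file; skipped", hyp$gene_id[i]))
      next
    }
    model <- trimLowConfidence(parseStructure(p), config$plddtMin)
    if (nResidues(model) < 20L) {
      say(sprintf("[structure] %s: fewer than 20 confident residues; skipped",
                  hyp$gene_id[i]))
      next
    }
    screened <- screenByStructure(model, refs, config$tmMin)
    top <- screened[[1]]
    keep[i] <- attr(screened, "pass")
    bestRef[i] <- names(screened)[1]
    bestTm[i] <- tmScoreOf(top)
    bestRmsd[i] <- rmsdOf(top)
    if (keep[i]) {
      sups[[hyp$gene_id[i]]] <- top
      models[[hyp$gene_id[i]]] <- model
    }
    say(sprintf("[structure] %s vs %s: TM %.3f RMSD %.2f -> %s",
                hyp$gene_id[i], bestRef[i], bestTm[i], bestRmsd[i],
                if (keep[i]) "pass" else "fail"))
  }
  struct <- hyp[keep, , drop = FALSE]
  struct$best_ref <- bestRef[keep]
  struct$tm_score <- bestTm[keep]
  struct$rmsd <- bestRmsd[keep]
  nStruct <- nrow(struct)

  # known-TPS exclusion
  seqs <- stats::setNames(struct$protein_seq, struct$gene_id)
  kept <- excludeKnownTps(seqs, knownTps, scheme, config$knownTpsEMax)
  audit <- attr(kept, "audit")
  final <- struct[struct$gene_id %in% names(kept), , drop = FALSE]
  final$known_tps_evalue <- unname(audit[final$gene_id])
  nFinal <- nrow(final)

  # typing across genomes
  typing <- if (nFinal) {
    clusterTypes(pairwiseEvalues(stats::setNames(final$protein_seq,
                                                 final$gene_id), scheme),
                 config$typeEMax)
  } else new("TypePartition", clusters = list(), threshold = config$typeEMax)
  typeOf <- stats::setNames(rep(names(typeClusters(typing)),
                                lengths(typeClusters(typing))),
                            unlist(typeClusters(typing), use.names = FALSE))
  final$type <- if (nFinal) unname(typeOf[final$gene_id]) else character(0)

  # active-site proximity motifs against each candidate's best reference
  motifs <- list()
  motifStrings <- character(nFinal)
  if (!is.null(config$catalyticRefs)) {
    for (i in seq_len(nFinal)) {
      gid <- final$gene_id[i]
      refId <- final$best_ref[i]
      catRef <- config$catalyticRefs[[refId]]
      if (is.null(catRef)) next
      prox <- mapProximalResidues(models[[gid]], refs[[refId]], sups[[gid]],
                                  catRef, config$proximityCutoff)
      mot <- extractMotifs(prox)
      motifs[[gid]] <- list(proximal = prox, motifs = mot)
      motifStrings[i] <- paste(mot$pattern, collapse = ",")
    }
  }
  final$motifs <- motifStrings
  final$length <- nchar(final$protein_seq)

  cols <- c("genome_id", "contig_id", "gene_id", "offset", "anchor_gene_id",
            "anchor_evalue", "product", "length", "best_ref", "tm_score",
            "rmsd", "known_tps_evalue", "type", "motifs")
  final <- final[order(final$genome_id, final$contig_id, final$gene_id),
                 cols, drop = FALSE]
  rownames(final) <- NULL

  new("CandidateReport", candidates = final,
      stageCounts = c(window = nWindow, hypothetical = nHyp,
                      structure = nStruct, known_tps = nFinal),
      typing = typing, motifs = motifs,
      superpositions = sups[final$gene_id], config = unclass(config))
}

#' Homolog census and phylogeny per candidate type
#'
#' For every type in the report: searches the protein database with the
#' type representative (the longest member sequence), counts homologs below
#' the census cutoff (and distinct organisms when headers carry
#' \code{[Organism]} tokens), and, when representative plus homologs give at
#' least 3 taxa, builds an identity-distance neighbor-joining tree.
#'
#' @param report a [CandidateReport-class] from [runMining()].
#' @param proteinDb named character vector or \code{AAStringSet}.
#' @param config the [miningConfig()] of the run.
#' @return list with \code{table} (type, representative, n_homologs,
#'   n_species) and \code{trees} (named list of \code{phylo} or NULL, with
#'   Newick strings as the \code{"newick"} attribute of each tree).
#' @export
runHomologCensus <- function(report, proteinDb, config) {
  if (methods::is(proteinDb, "XStringSet"))
    proteinDb <- stats::setNames(as.character(proteinDb), names(proteinDb))
  cand <- candidateTable(report)
  if (!nrow(cand)) stop("report has no candidates")
  clusters <- typeClusters(report)
  allSeqs <- .candidate_sequences(report)

  rows <- list(); trees <- list()
  for (ty in names(clusters)) {
    members <- clusters[[ty]]
    memberSeqs <- allSeqs[members]
    rep_id <- members[which.max(nchar(memberSeqs))]
    repSeq <- memberSeqs[[rep_id]]
    hits <- findHomologs(repSeq, proteinDb, config$scheme,
                         eMax = config$homologEMax, queryId = rep_id)
    sp <- attr(hits, "speciesCounts")
    rows[[ty]] <- data.frame(type = ty, representative = rep_id,
                             n_homologs = nrow(hits),
                             n_species = if (is.null(sp)) NA_integer_ else length(sp),
                             stringsAsFactors = FALSE)
    taxa <- c(stats::setNames(repSeq, rep_id),
              stats::setNames(proteinDb[hits$sseqid], hits$sseqid))
    taxa <- taxa[!duplicated(names(taxa))]
    if (length(taxa) >= 3L) {
      tree <- neighborJoining(distanceMatrix(taxa, config$scheme))
      attr(tree, "newick") <- writeNewick(tree)
      trees[[ty]] <- tree
    } else {
      message("type ", ty, ": fewer than 3 taxa; tree skipped")
      trees[ty] <- list(NULL)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, trees = trees)
}

# candidate protein sequences of a report, keyed by gene id
.candidate_sequences <- function(report) {
  cfg <- report@config
  seqs <- character(0)
  for (gb in cfg$genomes) {
    g <- geneTable(parseGenBank(gb))
    found <- intersect(candidateTable(report)$gene_id, g$gene_id)
    if (length(found))
      seqs <- c(seqs, stats::setNames(
        g$protein_seq[match(found, g$gene_id)], found))
  }
  seqs
}

#' Write a candidate report to disk
#'
#' Emits \code{report.tsv}, \code{report.json}, \code{types.tsv} and
#' \code{motifs.json} with fully specified ordering so identical runs give
#' byte-identical files.
#'
#' @param report a [CandidateReport-class].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cand <- candidateTable(report)
  utils::write.table(cand, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(stage_counts = as.list(stageCounts(report)),
         candidates = cand),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE)
  writeTypesTsv(report@typing, file.path(dir, "types.tsv"))
  jsonlite::write_json(
    lapply(motifTables(report), function(x)
      list(proximal = x$proximal,
           motifs = x$motifs[, c("pattern", "start", "end")])),
    file.path(dir, "motifs.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
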