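#' @include structure-io.R scoring.R genome-io.R
NULL

# evaluate expr with a local RNG state seeded by `seed`
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# helix-forming residues get higher weight in structured fixture proteins
.random_protein <- function(n, helical = FALSE) {
  w <- rep(1, 20)
  names(w) <- .AA20
  if (helical) w[c("A", "L", "E", "M", "Q", "K", "R", "H")] <- 3
  paste(sample(.AA20, n, replace = TRUE, prob = w / sum(w)), collapse = "")
}

# uniform random proper rotation via quaternions
.random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Ideal antiparallel helical bundle (Calpha trace)
#'
#' Generates an idealized alpha-helical bundle: each helix uses canonical
#' Calpha geometry (1.5 Angstrom rise and 100 degrees rotation per residue
#' on a 2.3 Angstrom radius), helices alternate direction and sit on a
#' circle of radius 8 Angstrom, and consecutive helices are joined by
#' 4-residue linear loops. A small seeded jitter (sd 0.05 Angstrom)
#' distinguishes bundles built from different seeds. Deterministic per seed.
#'
#' @param nHelices number of helices (>= 2).
#' @param helixLen residues per helix (>= 10).
#' @param seed RNG seed for the jitter and the residue letters.
#' @param modelId identifier of the resulting model.
#' @return a [StructureModel-class] with
#'   \code{nHelices * helixLen + (nHelices - 1) * 4} residues, confidence 95.
#' @export
makeHelicalBundle <- function(nHelices = 4L, helixLen = 25L, seed = 1L,
                              modelId = sprintf("bundle%dx%d-s%d", nHelices,
                                                helixLen, seed)) {
  stopifnot(nHelices >= 2L, helixLen >= 10L)
  .with_seed(seed, {
    rise <- 1.5; twist <- 100 * pi / 180; rad <- 2.3; ring <- 8; loopLen <- 4L
    coords <- NULL
    prevEnd <- NULL
    for (h in seq_len(nHelices)) {
      theta <- 2 * pi * (h - 1) / nHelices
      center <- c(ring * cos(theta), ring * sin(theta), 0)
      dirz <- if (h %% 2L == 1L) 1 else -1
      i <- seq_len(helixLen) - 1L
      local <- cbind(rad * cos(twist * i), rad * sin(twist * i),
                     dirz * (rise * i - rise * helixLen / 2))
      hel <- sweep(local, 2, center, "+")
      if (!is.null(prevEnd)) {
        w <- seq_len(loopLen) / (loopLen + 1)
        loop <- outer(1 - w, prevEnd) + outer(w, hel[1, ])
        coords <- rbind(coords, loop)
      }
      coords <- rbind(coords, hel)
      prevEnd <- hel[helixLen, ]
    }
    coords <- coords + matrix(stats::rnorm(length(coords), sd = 0.05),
                              nrow(coords), 3)
    aa <- strsplit(.random_protein(nrow(coords), helical = TRUE), "")[[1]]
    structureModel(modelId, coords, aa = aa,
                   confidence = rep(95, nrow(coords)))
  })
}

#' Fully extended Calpha chain (fold-mismatch decoy)
#'
#' A zigzag chain with ~3.8 Angstrom between consecutive Calpha atoms and no
#' tertiary contacts; used as a decoy that no compact reference fold should
#' match.
#'
#' @param n number of residues.
#' @param seed RNG seed for residue letters and jitter.
#' @param modelId identifier.
#' @return a [StructureModel-class] with confidence 92.
#' @export
makeExtendedChain <- function(n, seed = 1L, modelId = sprintf("ext%d-s%d", n, seed)) {
  .with_seed(seed, {
    i <- seq_len(n) - 1L
    coords <- cbind(3.3 * i, 1.9 * (i %% 2), 0) +
      matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
    aa <- strsplit(.random_protein(n), "")[[1]]
    structureModel(modelId, coords, aa = aa, confidence = rep(92, n))
  })
}

#' Perturb a structure model
#'
#' Adds isotropic Gaussian noise (sd \code{sigma} per axis) to every Calpha
#' and then applies a random proper rigid transform. Confidence is set to 90
#' throughout (predicted-model convention).
#'
#' @param m a [StructureModel-class].
#' @param sigma noise standard deviation per axis in Angstrom (>= 0).
#' @param seed RNG seed.
#' @param modelId identifier of the perturbed model.
#' @return a [StructureModel-class].
#' @export
perturbStructure <- function(m, sigma, seed = 1L, modelId = NULL) {
  stopifnot(sigma >= 0)
  if (is.null(modelId)) modelId <- paste0(m@modelId, "-pert")
  .with_seed(seed, {
    xyz <- caCoords(m)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = sigma), nrow(xyz), 3)
    R <- .random_rotation()
    t <- stats::runif(3, -20, 20)
    xyz <- sweep(xyz %*% R, 2, t, "+")
    structureModel(modelId, xyz, aa = residueLetters(m),
                   resIndex = residueIndices(m),
                   confidence = rep(90, nResidues(m)))
  })
}

#' Mutate a protein to a target identity
#'
#' Substitutes a Bernoulli(1 - targetIdentity) fraction of positions,
#' preferring BLOSUM-plausible (positive-scoring) replacement letters, so the
#' mutant stays detectable as a homolog. No indels unless \code{indelRate}
#' is positive. Deterministic per seed.
#'
#' @param seq protein sequence.
#' @param targetIdentity expected fraction of unchanged positions, in (0, 1].
#' @param seed RNG seed.
#' @param indelRate per-position probability of a single-residue insertion
#'   or deletion (default 0).
#' @param scheme scoring scheme supplying the substitution matrix.
#' @return the mutated protein sequence.
#' @export
mutateProtein <- function(seq, targetIdentity, seed = 1L, indelRate = 0,
                          scheme = defaultScheme()) {
  stopifnot(targetIdentity > 0, targetIdentity <= 1)
  if (targetIdentity == 1 && indelRate == 0) return(seq)
  .with_seed(seed, {
    m <- scheme@matrix
    aa <- strsplit(seq, "")[[1]]
    for (i in seq_along(aa)) {
      if (stats::runif(1) < 1 - targetIdentity) {
        row <- m[aa[i], .AA20]
        pool <- setdiff(names(row)[row > 0], aa[i])
        if (!length(pool)) pool <- setdiff(.AA20, aa[i])
        aa[i] <- sample(pool, 1L)
      }
    }
    if (indelRate > 0) {
      out <- character(0)
      for (i in seq_along(aa)) {
        u <- stats::runif(1)
        if (u < indelRate / 2) next                       # deletion
        out <- c(out, aa[i])
        if (u >= indelRate / 2 && u < indelRate)
          out <- c(out, sample(.AA20, 1L))                # insertion
      }
      aa <- out
    }
    paste(aa, collapse = "")
  })
}

# ---- whole-genome fixtures --------------------------------------------------

.PRODUCT_POOL <- c(
  "ABC transporter ATP-binding protein", "DNA polymerase III subunit beta",
  "MFS transporter", "two-component sensor histidine kinase",
  "ribosomal protein L3", "acyl-CoA dehydrogenase",
  "TetR family transcriptional regulator", "aminotransferase class V",
  "NADH-quinone oxidoreductase subunit", "peptidoglycan glycosyltransferase",
  "geranylgeranyl diphosphate synthase", "sigma-70 family RNA polymerase factor")

#' Reference set for synthetic fixtures
#'
#' Generates, deterministically per seed, the shared references a mining run
#' needs: one synthetic E-IDS anchor protein, three synthetic known-TPS
#' protein sequences, a candidate-family parent protein, three synthetic
#' reference TPS structures (stand-ins for the class I / IB / IC reference
#' folds), and a catalytic-residue reference per structure (the six residues
#' closest to the bundle core).
#'
#' @param seed RNG seed.
#' @return list with \code{eids}, \code{knownTps}, \code{candidateParent}
#'   (sequences), \code{refStructures} (named list of
#'   [StructureModel-class]), \code{catalyticRefs} (named list of
#'   [catalyticReference()] tables).
#' @export
fixtureReferences <- function(seed = 42L) {
  .with_seed(seed, {
    eids <- c(EIDS_ref = .random_protein(350))
    knownTps <- c(knownTPS_1 = .random_protein(300, helical = TRUE),
                  knownTPS_2 = .random_protein(300, helical = TRUE),
                  knownTPS_3 = .random_protein(280, helical = TRUE))
    candidateParent <- .random_protein(320, helical = TRUE)
    refStructures <- list(
      `classI-syn`  = makeHelicalBundle(6L, 22L, seed = seed,      modelId = "classI-syn"),
      `classIB-syn` = makeHelicalBundle(5L, 20L, seed = seed + 1L, modelId = "classIB-syn"),
      `classIC-syn` = makeHelicalBundle(4L, 24L, seed = seed + 2L, modelId = "classIC-syn"))
    catalyticRefs <- lapply(refStructures, function(m) {
      xyz <- caCoords(m)
      d <- sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
      pick <- sort(residueIndices(m)[order(d)[1:6]])
      at <- match(pick, residueIndices(m))
      catalyticReference(modelId(m), pick, aa = residueLetters(m)[at],
                         role = "core")
    })
    list(eids = eids, knownTps = knownTps, candidateParent = candidateParent,
         refStructures = refStructures, catalyticRefs = catalyticRefs)
  })
}

#' Specification of one synthetic genome
#'
#' @param seed RNG seed of the genome.
#' @param nContigs number of contigs.
#' @param genesPerContig CDS per contig.
#' @param window gene-count window the fixture is built for (candidate
#'   offsets must fit inside it).
#' @param planted list of planted elements; each entry has \code{role}
#'   (anchor, candidate, known_tps_decoy, far_hypothetical), optional
#'   \code{offset} (rank difference from the anchor), \code{sigma}
#'   (structure noise, Angstrom) and \code{identity} (sequence identity to
#'   the parent). The defaults plant one of each: the candidate 3 genes
#'   downstream of the anchor, the decoy 2 genes upstream, and a
#'   hypothetical protein outside the window.
#' @return a \code{FixtureSpec} list.
#' @export
fixtureSpec <- function(seed = 1L, nContigs = 1L, genesPerContig = 28L,
                        window = 10L,
                        planted = list(
                          list(role = "anchor", identity = 0.7),
                          list(role = "candidate", offset = 3L,
                               sigma = 1.0, identity = 0.7),
                          list(role = "known_tps_decoy", offset = -2L,
                               sigma = 1.0, identity = 0.7),
                          list(role = "far_hypothetical", offset = 14L))) {
  spec <- list(seed = as.integer(seed), nContigs = as.integer(nContigs),
               genesPerContig = as.integer(genesPerContig),
               window = as.integer(window), planted = planted)
  roles <- vapply(planted, `[[`, character(1), "role")
  for (p in planted) {
    if (p$role == "candidate" && abs(p$offset) > spec$window)
      stop("candidate offset ", p$offset, " exceeds the window ", spec$window)
    if (p$role == "far_hypothetical" && abs(p$offset) <= spec$window)
      stop("far_hypothetical offset ", p$offset, " lies inside the window")
  }
  if (sum(roles == "anchor") != 1L)
    stop("exactly one anchor must be planted")
  class(spec) <- "FixtureSpec"
  spec
}

# reverse-translate a protein with random synonymous codons (table 11)
.reverse_translate <- function(prot) {
  code <- Biostrings::getGeneticCode("11")
  byAA <- split(names(code), code)
  aa <- strsplit(prot, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- byAA[[a]]
    if (is.null(opts)) "NNN" else if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste0(paste(codons, collapse = ""), sample(c("TAA", "TGA", "TAG"), 1L))
}

# minimal GenBank flat-file writer for fixture genomes
.write_genbank <- function(contigs, genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ct in names(contigs)) {
    nt <- tolower(contigs[[ct]])
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT", ct,
                       nchar(nt)), con)
    writeLines(sprintf("DEFINITION  synthetic fixture contig %s.", ct), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    g <- genes[genes$contig_id == ct, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      loc <- sprintf("%d..%d", g$start[i] + 1L, g$end[i])
      if (g$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     CDS             %s", loc), con)
      writeLines(sprintf('                     /locus_tag="%s"', g$gene_id[i]), con)
      writeLines(sprintf('                     /product="%s"', g$product[i]), con)
      tr <- g$protein_seq[i]
      chunks <- substring(tr, seq(1, nchar(tr), 44), pmin(seq(1, nchar(tr), 44) + 43, nchar(tr)))
      writeLines(sprintf('                     /translation="%s"',
                         paste(chunks, collapse = "\n                     ")), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1, nchar(nt), 60)
    for (p in pos) {
      seg <- substr(nt, p, min(p + 59, nchar(nt)))
      grp <- substring(seg, seq(1, nchar(seg), 10), pmin(seq(1, nchar(seg), 10) + 9, nchar(seg)))
      writeLines(sprintf("%9d %s", p, paste(grp, collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Generate a synthetic genome with planted ground truth
#'
#' Builds a GenBank flat file, a directory of per-gene Calpha structure
#' models, and a truth table, emulating the inputs of the mining workflow:
#' the planted anchor is a mutated copy of the reference E-IDS; the planted
#' candidate is a hypothetical-annotated gene at the stated offset whose
#' structure is a noisy copy of the class I reference fold; the known-TPS
#' decoy is hypothetical-annotated, structure-similar to the reference fold
#' and sequence-similar to the known-TPS set (so only the sequence-exclusion
#' filter removes it); the far hypothetical sits outside the window and has
#' an extended-chain structure; all remaining genes carry informative
#' product annotations and random sequences.
#'
#' @param spec a [fixtureSpec()].
#' @param refs a [fixtureReferences()] list.
#' @param dir output directory (created if needed).
#' @param genomeId genome identifier; default derived from the seed.
#' @return list with \code{genbank} (path), \code{structuresDir} (path),
#'   \code{truth} (data.frame: gene_id, role, offset, sigma, identity),
#'   \code{annotation} (the [GenomeAnnotation-class] as built).
#' @export
makeSyntheticGenome <- function(spec, refs = fixtureReferences(),
                                dir = tempfile("fixture"),
                                genomeId = sprintf("syng%03d", spec$seed)) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structDir <- file.path(dir, paste0(genomeId, "_structures"))
  dir.create(structDir, showWarnings = FALSE)

  .with_seed(spec$seed * 1000L + 7L, {
    nGenes <- spec$nContigs * spec$genesPerContig
    anchorPos <- ceiling(spec$genesPerContig / 2)  # 1-based index on contig 1

    roles <- rep("unrelated", nGenes)
    offsets <- rep(NA_integer_, nGenes)
    sigmas <- rep(NA_real_, nGenes)
    idents <- rep(NA_real_, nGenes)
    roles[anchorPos] <- "anchor"
    offsets[anchorPos] <- 0L
    for (p in spec$planted) {
      if (p$role == "anchor") { idents[anchorPos] <- p$identity %||% 0.7; next }
      pos <- anchorPos + p$offset
      if (pos < 1L || pos > spec$genesPerContig)
        stop("planted offset ", p$offset, " falls off contig 1")
      roles[pos] <- p$role
      offsets[pos] <- as.integer(p$offset)
      sigmas[pos] <- p$sigma %||% NA_real_
      idents[pos] <- p$identity %||% NA_real_
    }

    geneRows <- list()
    contigSeqs <- list()
    structures <- list()
    gidx <- 0L
    for (ct in seq_len(spec$nContigs)) {
      contig <- sprintf("%s_c%d", genomeId, ct)
      cursor <- 0L
      ntParts <- character(0)
      for (k in seq_len(spec$genesPerContig)) {
        gidx <- gidx + 1L
        i <- if (ct == 1L) k else nGenes + 1L  # planted roles only on contig 1
        role <- if (ct == 1L) roles[k] else "unrelated"
        geneId <- sprintf("%s_g%02d", genomeId, gidx)
        prot <- switch(role,
          anchor = mutateProtein(refs$eids[[1]], idents[k] %||% 0.7,
                                 seed = spec$seed * 100L + gidx),
          candidate = mutateProtein(refs$candidateParent, idents[k],
                                    seed = spec$seed * 100L + gidx),
          known_tps_decoy = mutateProtein(refs$knownTps[[1]], idents[k],
                                          seed = spec$seed * 100L + gidx),
          far_hypothetical = .random_protein(200),
          .random_protein(sample(150:250, 1L)))
        # start every fixture protein with M: CDS begin at a start codon, so
        # translations round-trip through the initiator-to-M convention
        prot <- paste0("M", substr(prot, 2L, nchar(prot)))
        product <- switch(role,
          anchor = "polyprenyl diphosphate synthase",
          candidate = "hypothetical protein",
          known_tps_decoy = "hypothetical protein",
          far_hypothetical = "hypothetical protein",
          sample(.PRODUCT_POOL, 1L))
        if (role == "candidate")
          structures[[geneId]] <- perturbStructure(
            refs$refStructures[[1]], sigmas[k], seed = spec$seed * 100L + gidx,
            modelId = geneId)
        if (role == "known_tps_decoy")
          structures[[geneId]] <- perturbStructure(
            refs$refStructures[[1]], sigmas[k], seed = spec$seed * 100L + gidx + 1L,
            modelId = geneId)
        if (role == "far_hypothetical")
          structures[[geneId]] <- makeExtendedChain(
            112L, seed = spec$seed * 100L + gidx, modelId = geneId)

        spacer <- paste(sample(c("A", "C", "G", "T"),
                               sample(20:80, 1L), replace = TRUE), collapse = "")
        cds <- .reverse_translate(prot)
        strand <- sample(c("+", "-"), 1L)
        seg <- if (strand == "-")
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds))) else cds
        start0 <- cursor + nchar(spacer)              # 0-based
        ntParts <- c(ntParts, spacer, seg)
        cursor <- start0 + nchar(seg)
        geneRows[[gidx]] <- data.frame(
          gene_id = geneId, contig_id = contig, start = start0,
          end = start0 + nchar(seg), strand = strand, product = product,
          protein_seq = prot, rank = 0L, role = role,
          offset = if (ct == 1L) offsets[k] else NA_integer_,
          sigma = if (ct == 1L) sigmas[k] else NA_real_,
          identity = if (ct == 1L) idents[k] else NA_real_,
          stringsAsFactors = FALSE)
      }
      contigSeqs[[contig]] <- paste(ntParts, collapse = "")
    }

    genes <- do.call(rbind, geneRows)
    gbPath <- file.path(dir, paste0(genomeId, ".gbk"))
    .write_genbank(contigSeqs, genes, gbPath)
    for (gid in names(structures))
      writeStructurePdb(structures[[gid]], file.path(structDir, paste0(gid, ".pdb")))

    truth <- genes[genes$role != "unrelated",
                   c("gene_id", "role", "offset", "sigma", "identity")]
    rownames(truth) <- NULL
    utils::write.table(truth, file.path(dir, paste0(genomeId, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ann <- .build_annotation(genomeId,
                             genes[, .GENE_COLS],
                             {
                               d <- Biostrings::DNAStringSet(unlist(contigSeqs))
                               names(d) <- names(contigSeqs)
                               d
                             })
    list(genbank = gbPath, structuresDir = structDir, truth = truth,
         annotation = ann, genomeId = genomeId)
  })
}

#' Generate a full fixture collection for a mining run
#'
#' Writes the shared references (E-IDS FASTA, known-TPS FASTA, reference
#' structure PDBs) and \code{nGenomes} synthetic genomes (each planting a
#' candidate from the same family) into one directory, and assembles the
#' matching [miningConfig()].
#'
#' @param dir output directory.
#' @param nGenomes number of genomes.
#' @param seed base RNG seed; genome g uses \code{seed * 1000 + g}.
#' @param refSeed seed of the shared reference set.
#' @param ... passed to [fixtureSpec()] for every genome.
#' @return list with \code{config} (a [miningConfig()]), \code{truths}
#'   (named list of per-genome truth tables) and \code{refs}.
#' @export
makeFixtureCollection <- function(dir, nGenomes = 20L, seed = 1L,
                                  refSeed = 42L, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- fixtureReferences(refSeed)

  eidsPath <- file.path(dir, "eids.faa")
  aa <- Biostrings::AAStringSet(refs$eids); names(aa) <- names(refs$eids)
  Biostrings::writeXStringSet(aa, eidsPath)
  knownPath <- file.path(dir, "known_tps.faa")
  aa <- Biostrings::AAStringSet(refs$knownTps); names(aa) <- names(refs$knownTps)
  Biostrings::writeXStringSet(aa, knownPath)

  refDir <- file.path(dir, "ref_structures")
  dir.create(refDir, showWarnings = FALSE)
  refPaths <- vapply(names(refs$refStructures), function(nm) {
    p <- file.path(refDir, paste0(nm, ".pdb"))
    writeStructurePdb(refs$refStructures[[nm]], p)
    p
  }, character(1))

  structRoot <- file.path(dir, "structures")
  dir.create(structRoot, showWarnings = FALSE)
  gbPaths <- character(0)
  truths <- list()
  for (g in seq_len(nGenomes)) {
    spec <- fixtureSpec(seed = seed * 1000L + g, ...)
    fx <- makeSyntheticGenome(spec, refs, dir = dir)
    # collect per-genome structure files under one root
    for (f in list.files(fx$structuresDir, full.names = TRUE))
      file.copy(f, file.path(structRoot, basename(f)), overwrite = TRUE)
    gbPaths <- c(gbPaths, fx$genbank)
    truths[[fx$genomeId]] <- fx$truth
  }

  config <- miningConfig(
    genomes = gbPaths, structures = structRoot, eidsFasta = eidsPath,
    knownTpsFasta = knownPath, refStructures = refPaths,
    catalyticRefs = refs$catalyticRefs, seed = seed)
  list(config = config, truths = truths, refs = refs)
}
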