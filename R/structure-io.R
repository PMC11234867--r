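#' @include AllClasses.R
NULL

.AA321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V")
.AA123 <- stats::setNames(names(.AA321), .AA321)

#' Build a StructureModel from its parts
#'
#' @param modelId identifier.
#' @param coords n x 3 numeric matrix of Calpha coordinates (Angstrom).
#' @param aa one-letter residue codes (default all \code{"A"}).
#' @param resIndex residue numbers (default 1..n).
#' @param confidence per-residue confidence in [0, 100], or NULL.
#' @return a [StructureModel-class].
#' @export
structureModel <- function(modelId, coords, aa = NULL, resIndex = NULL,
                           confidence = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(resIndex)) resIndex <- seq_len(n)
  if (is.null(confidence)) confidence <- numeric(0)
  dimnames(coords) <- NULL
  new("StructureModel", modelId = as.character(modelId),
      resIndex = as.integer(resIndex), aa = as.character(aa),
      coords = coords, confidence = as.numeric(confidence))
}

#' Parse a Calpha structure model from PDB or mmCIF
#'
#' Reads one chain (by default the first chain in file order) and keeps one
#' Calpha atom per residue; alternate locations are resolved by highest
#' occupancy, then alphabetically. When \code{confidence = "bfactor"} (the
#' default, appropriate for AlphaFold-style predicted models) the B-factor
#' column is stored as per-residue confidence; pass \code{"none"} for
#' experimental structures.
#'
#' @param path PDB (\code{.pdb}) or mmCIF (\code{.cif}, \code{.mmcif}) file.
#' @param chain chain identifier, or \code{"auto"} for the first chain.
#' @param confidence \code{"bfactor"} or \code{"none"}.
#' @return a [StructureModel-class].
#' @export
parseStructure <- function(path, chain = "auto",
                           confidence = c("bfactor", "none")) {
  confidence <- match.arg(confidence)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
    bio3d::read.cif(path) else bio3d::read.pdb(path)
  at <- pdb$atom
  ca <- at[at$elety == "CA" & !is.na(at$x), , drop = FALSE]
  if (!nrow(ca)) stop("no Calpha atoms in ", path)
  chains <- unique(ca$chain)
  if (identical(chain, "auto")) {
    chain <- chains[1]
  } else if (!chain %in% chains) {
    stop("chain ", chain, " absent from ", path, "; available: ",
         paste(chains, collapse = ", "))
  }
  ca <- ca[ca$chain %in% chain, , drop = FALSE]

  # resolve altlocs: highest occupancy, then alphabetical altloc
  occ <- if (!is.null(ca$o)) ifelse(is.na(ca$o), 1, ca$o) else rep(1, nrow(ca))
  alt <- if (!is.null(ca$alt)) ifelse(is.na(ca$alt), "", ca$alt) else rep("", nrow(ca))
  ord <- order(ca$resno, -occ, alt)
  ca <- ca[ord, , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]

  aa <- unname(.AA321[ca$resid])
  aa[is.na(aa)] <- "X"
  conf <- if (confidence == "bfactor" && !all(is.na(ca$b)))
    pmin(pmax(ca$b, 0), 100) else NULL
  structureModel(sub("\\.(pdb|cif|mmcif)$", "", basename(path), ignore.case = TRUE),
                 cbind(ca$x, ca$y, ca$z), aa = aa, resIndex = ca$resno,
                 confidence = conf)
}

#' Remove low-confidence residues from a predicted model
#'
#' Drops residues whose confidence (pLDDT) is below \code{plddtMin}; the
#' original residue numbering is preserved. If the model carries no
#' confidence values it is returned unchanged with a warning.
#'
#' @param m a [StructureModel-class].
#' @param plddtMin confidence cutoff in [0, 100] (default 70).
#' @return a trimmed [StructureModel-class].
#' @export
trimLowConfidence <- function(m, plddtMin = 70) {
  stopifnot(plddtMin >= 0, plddtMin <= 100)
  conf <- confidences(m)
  if (!length(conf)) {
    warning("model ", modelId(m), " has no confidence values; returned unchanged")
    return(m)
  }
  keep <- conf >= plddtMin
  structureModel(modelId(m), caCoords(m)[keep, , drop = FALSE],
                 aa = residueLetters(m)[keep],
                 resIndex = residueIndices(m)[keep],
                 confidence = conf[keep])
}

#' Write a Calpha model as a PDB file
#'
#' One ATOM record per residue; confidence (when present) goes to the
#' B-factor column, mirroring predicted-model conventions.
#'
#' @param m a [StructureModel-class].
#' @param path output path.
#' @param transform optional [Superposition-class]; when given, coordinates
#'   are written after applying its rotation and translation.
#' @return the path, invisibly.
#' @export
writeStructurePdb <- function(m, path, transform = NULL) {
  xyz <- caCoords(m)
  if (!is.null(transform))
    xyz <- applySuperposition(xyz, transform)
  conf <- confidences(m)
  if (!length(conf)) conf <- rep(0, nResidues(m))
  res3 <- .AA123[residueLetters(m)]
  res3[is.na(res3)] <- "UNK"
  lines <- sprintf(
    "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nResidues(m)), res3, residueIndices(m),
    xyz[, 1], xyz[, 2], xyz[, 3], 1.00, conf)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
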