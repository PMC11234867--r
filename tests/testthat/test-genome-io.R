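test_that("translateCds follows the bacterial code conventions", {
  expect_equal(translateCds("ATGGCAACC"), "MAT")
  expect_equal(translateCds("ATGNNNTAA"), "MX")
  expect_equal(translateCds("GTGGCA"), "MA")    # alternative initiator
  expect_equal(translateCds("TTGGCA"), "MA")
  expect_equal(translateCds("ATGGCAAC"), "MA")  # trailing partial codon trimmed
  expect_error(translateCds("AT!GCA"))
})

test_that("parseGenBank maps CDS features, strands and ranks", {
  gb <- c(
    "LOCUS       ctg1 300 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..18",
    '                     /locus_tag="gA"',
    '                     /product="hypothetical protein"',
    '                     /translation="MAT"',
    "     CDS             complement(100..199)",
    '                     /locus_tag="gB"',
    '                     /product="MFS transporter"',
    '                     /translation="M"',
    "     CDS             250..258",
    '                     /locus_tag="gC"',
    '                     /translation="MAA"',
    "ORIGIN",
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)
  ann <- parseGenBank(path)
  g <- geneTable(ann)
  expect_equal(nrow(g), 3L)
  expect_equal(g$rank, 0:2)
  # complement(100..199) in 0-based half-open coordinates
  expect_equal(g$start[g$gene_id == "gB"], 99L)
  expect_equal(g$end[g$gene_id == "gB"], 199L)
  expect_equal(g$strand[g$gene_id == "gB"], "-")
  expect_equal(g$product[g$gene_id == "gC"], "")
})

test_that("parseGenBank computes missing translations from the origin sequence", {
  nt <- paste(c(rep("acgtacgtacgt", 2), "atggcaacctaa", rep("ac", 10)),
              collapse = "")
  gb <- c(
    "LOCUS       ctg2 56 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             25..36",
    '                     /locus_tag="gX"',
    "ORIGIN",
    sprintf("%9d %s", 1, nt),
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)
  g <- geneTable(parseGenBank(path))
  # oracle: independent extraction + translation of the span
  span <- toupper(substr(nt, 25, 36))
  expect_equal(g$protein_seq, translateCds(span))
  expect_equal(g$protein_seq, "MAT")
})

test_that("unresolvable CDS locations are skipped with a warning, not an abort", {
  gb <- c(
    "LOCUS       ctg3 100 bp    DNA     linear   BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(other.1:1..9,20..40)",
    '                     /locus_tag="bad"',
    "     CDS             10..18",
    '                     /locus_tag="good"',
    '                     /translation="MAT"',
    "ORIGIN",
    "//")
  path <- withr::local_tempfile(fileext = ".gbk")
  writeLines(gb, path)
  expect_warning(ann <- parseGenBank(path), "unresolvable")
  expect_equal(geneTable(ann)$gene_id, "good")
})

test_that("parseGffFasta converts coordinates and splices multi-segment CDS", {
  fa <- withr::local_tempfile(fileext = ".fa")
  # chr1: gene g1 at 10..18 (+), g2 spliced from two segments, g3 on minus
  seq1 <- paste0(strrep("A", 9), "ATGGCAACC",            # 10..18  -> MAT
                 strrep("C", 3),
                 "ATGGCA", strrep("G", 4), "GAATGA",     # 22..27 + 32..37
                 strrep("T", 3),
                 "TTACATGGTCAT",                         # 41..52 (-) revcomp -> ATGACCATGTAA -> MTM
                 strrep("A", 8))
  writeLines(c(">chr1", seq1), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\t.\tCDS\t10\t18\t.\t+\t0\tID=g1;product=hypothetical protein",
    "chr1\t.\tCDS\t22\t27\t.\t+\t0\tID=g2a;Parent=m2",
    "chr1\t.\tCDS\t32\t37\t.\t+\t0\tID=g2b;Parent=m2",
    "chr1\t.\tCDS\t41\t52\t.\t-\t0\tID=g3"), gff)
  ann <- parseGffFasta(gff, fa)
  g <- geneTable(ann)
  expect_equal(nrow(g), 3L)
  expect_equal(g$start[g$gene_id == "g1"], 9L)   # 1-based 10 -> 0-based 9
  expect_equal(g$end[g$gene_id == "g1"], 18L)
  expect_equal(g$protein_seq[g$gene_id == "g1"], "MAT")
  # joined translation across the two segments of m2
  spliced <- paste0(substr(seq1, 22, 27), substr(seq1, 32, 37))
  expect_equal(g$protein_seq[g$gene_id == "m2"], translateCds(spliced))
  # minus-strand translation equals revcomp oracle
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(seq1, 41, 52))))
  expect_equal(g$protein_seq[g$gene_id == "g3"], translateCds(rc))
  expect_error(parseGffFasta(gff, {
    fa2 <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">other", "ACGT"), fa2); fa2
  }), "chr1")
})

test_that("GFF3+FASTA round trip reproduces the gene table field by field", {
  fx <- makeSyntheticGenome(fixtureSpec(seed = 31L), fixtureReferences(42L),
                            dir = withr::local_tempdir())
  ann <- fx$annotation
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeGenomeGff(ann, gff, fa)
  back <- parseGffFasta(gff, fa, genomeId = genomeId(ann))
  a <- geneTable(ann); b <- geneTable(back)
  b <- b[match(a$gene_id, b$gene_id), ]
  rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("GenBank and GFF3 renderings of the same genome parse identically", {
  fx <- makeSyntheticGenome(fixtureSpec(seed = 32L), fixtureReferences(42L),
                            dir = withr::local_tempdir())
  fromGb <- parseGenBank(fx$genbank, genomeId = "same")
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fa")
  writeGenomeGff(fx$annotation, gff, fa)
  fromGff <- parseGffFasta(gff, fa, genomeId = "same")
  expect_equal(geneTable(fromGb), geneTable(fromGff))
})

test_that("protein FASTA export carries genome|contig|gene|rank headers", {
  fx <- makeSyntheticGenome(fixtureSpec(seed = 33L), fixtureReferences(42L),
                            dir = withr::local_tempdir())
  out <- withr::local_tempfile(fileext = ".faa")
  writeProteinFasta(fx$annotation, out)
  aa <- Biostrings::readAAStringSet(out)
  g <- geneTable(fx$annotation)
  expect_equal(length(aa), nrow(g))
  expect_equal(names(aa)[1],
               sprintf("%s|%s|%s|%d", genomeId(fx$annotation),
                       g$contig_id[1], g$gene_id[1], g$rank[1]))
})
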