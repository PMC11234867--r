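test_that("helical bundles have the stated size and helix geometry", {
  b <- makeHelicalBundle(4, 25, seed = 1)
  expect_equal(nResidues(b), 4 * 25 + 3 * 4)   # 112
  xyz <- caCoords(b)
  # consecutive Calpha distances inside each helix are ~3.8 A
  helixLen <- 25L; loopLen <- 4L
  for (h in 0:3) {
    rows <- h * (helixLen + loopLen) + seq_len(helixLen)
    d <- sqrt(rowSums(diff(xyz[rows, ])^2))
    expect_true(all(abs(d - 3.8) < 0.25))
  }
  # determinism per seed; different seeds differ
  expect_identical(caCoords(makeHelicalBundle(4, 25, seed = 1)), xyz)
  expect_false(identical(caCoords(makeHelicalBundle(4, 25, seed = 2)), xyz))
})

test_that("extended chains keep ~3.8 A spacing and stay elongated", {
  e <- makeExtendedChain(50, seed = 3)
  d <- sqrt(rowSums(diff(caCoords(e))^2))
  expect_true(all(abs(d - 3.8) < 0.3))
  span <- diff(range(caCoords(e)[, 1]))
  expect_gt(span, 100)   # no compact fold
})

test_that("perturbStructure matches the chi-distribution RMSD expectation", {
  b <- makeHelicalBundle(8, 22, seed = 5)   # 204 residues
  expect_equal(nResidues(b), 204L)
  # sigma = 0: exact superposition
  p0 <- perturbStructure(b, 0, seed = 6)
  s0 <- kabsch(caCoords(p0), caCoords(b))
  expect_equal(s0$rmsd, 0, tolerance = 1e-8)
  # sigma = 0.5: RMSD ~ 0.5 * sqrt(3) within 10%
  p <- perturbStructure(b, 0.5, seed = 7)
  s <- kabsch(caCoords(p), caCoords(b))
  expect_equal(s$rmsd, 0.5 * sqrt(3), tolerance = 0.1)
  # monotone growth with sigma
  rmsds <- vapply(c(0.25, 0.5, 1, 2), function(sg)
    kabsch(caCoords(perturbStructure(b, sg, seed = 8)), caCoords(b))$rmsd,
    numeric(1))
  expect_true(all(diff(rmsds) > 0))
  expect_identical(caCoords(perturbStructure(b, 0.5, seed = 7)), caCoords(p))
})

test_that("mutateProtein hits the target identity and is deterministic", {
  set.seed(51)
  parent <- random_protein(300)
  expect_identical(mutateProtein(parent, 1.0, seed = 1), parent)
  mut <- mutateProtein(parent, 0.6, seed = 2)
  realized <- mean(strsplit(parent, "")[[1]] == strsplit(mut, "")[[1]])
  expect_lt(abs(realized - 0.6), 0.1)
  # binomial concentration: the mean over 10 seeds is within 0.03
  meanRealized <- mean(vapply(1:10, function(s) {
    m <- mutateProtein(parent, 0.6, seed = s)
    mean(strsplit(parent, "")[[1]] == strsplit(m, "")[[1]])
  }, numeric(1)))
  expect_lt(abs(meanRealized - 0.6), 0.03)
  expect_identical(mutateProtein(parent, 0.6, seed = 2), mut)
  expect_false(identical(mutateProtein(parent, 0.6, seed = 3), mut))
  # indels change length
  indel <- mutateProtein(parent, 0.9, seed = 4, indelRate = 0.1)
  expect_false(nchar(indel) == nchar(parent))
})

test_that("fixtureSpec validates planted offsets", {
  expect_error(fixtureSpec(planted = list(
    list(role = "anchor", identity = 0.7),
    list(role = "candidate", offset = 11L, sigma = 1, identity = 0.7))),
    "exceeds the window")
  expect_error(fixtureSpec(planted = list(
    list(role = "anchor", identity = 0.7),
    list(role = "far_hypothetical", offset = 5L))),
    "inside the window")
  expect_error(fixtureSpec(planted = list(
    list(role = "candidate", offset = 3L, sigma = 1, identity = 0.7))),
    "anchor")
})

test_that("makeSyntheticGenome plants one truth row per element and re-parses", {
  refs <- fixtureReferences(42L)
  fx <- makeSyntheticGenome(fixtureSpec(seed = 55L), refs,
                            dir = withr::local_tempdir())
  expect_setequal(fx$truth$role,
                  c("anchor", "candidate", "known_tps_decoy", "far_hypothetical"))
  expect_equal(nrow(fx$truth), 4L)

  ann <- parseGenBank(fx$genbank)
  g <- geneTable(ann)
  expect_equal(nrow(g), 28L)
  # planted genes sit at the stated rank offsets from the anchor
  anchorRank <- g$rank[g$gene_id == fx$truth$gene_id[fx$truth$role == "anchor"]]
  for (r in seq_len(nrow(fx$truth))) {
    rank <- g$rank[g$gene_id == fx$truth$gene_id[r]]
    expect_equal(rank - anchorRank, fx$truth$offset[r])
  }
  # structure files exist for candidate, decoy and far hypothetical
  withModels <- fx$truth$gene_id[fx$truth$role != "anchor"]
  expect_true(all(file.exists(
    file.path(fx$structuresDir, paste0(withModels, ".pdb")))))
  # generated files re-parse cleanly under their formats
  for (p in file.path(fx$structuresDir, paste0(withModels, ".pdb")))
    expect_s4_class(parseStructure(p), "StructureModel")
})

test_that("seeds vary sequences but not roles", {
  refs <- fixtureReferences(42L)
  fx1 <- makeSyntheticGenome(fixtureSpec(seed = 56L), refs,
                             dir = withr::local_tempdir())
  fx2 <- makeSyntheticGenome(fixtureSpec(seed = 57L), refs,
                             dir = withr::local_tempdir())
  expect_equal(fx1$truth$role, fx2$truth$role)
  expect_equal(fx1$truth$offset, fx2$truth$offset)
  s1 <- geneTable(fx1$annotation)$protein_seq
  s2 <- geneTable(fx2$annotation)$protein_seq
  expect_false(identical(s1, s2))
})

test_that("the planted candidate keeps its identity target to the parent", {
  refs <- fixtureReferences(42L)
  fx <- makeSyntheticGenome(fixtureSpec(seed = 58L), refs,
                            dir = withr::local_tempdir())
  g <- geneTable(fx$annotation)
  candSeq <- g$protein_seq[g$gene_id ==
                             fx$truth$gene_id[fx$truth$role == "candidate"]]
  realized <- mean(strsplit(candSeq, "")[[1]] ==
                     strsplit(refs$candidateParent, "")[[1]])
  expect_equal(realized, 0.7, tolerance = 0.1)
})
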