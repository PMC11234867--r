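test_that("parseStructure reads Calpha traces, chains and confidence", {
  pdb <- c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 90.10           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00 55.20           C",
    "ATOM      3  N   GLY A   2       4.500   1.000   0.000  1.00 50.00           N",
    "ATOM      4  CA  ASP A   3       7.600   0.000   0.000  1.00 33.30           C",
    "ATOM      5  CA  LEU B   1       0.000   5.000   0.000  1.00 80.00           C",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, path)
  m <- parseStructure(path)                 # chain auto -> first chain (A)
  expect_equal(nResidues(m), 3L)
  expect_equal(residueLetters(m), c("A", "G", "D"))
  expect_equal(confidences(m), c(90.1, 55.2, 33.3))
  mB <- parseStructure(path, chain = "B")
  expect_equal(nResidues(mB), 1L)
  expect_error(parseStructure(path, chain = "Z"), "available")
})

test_that("structure PDB writer round-trips through the parser", {
  b <- makeHelicalBundle(3, 12, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeStructurePdb(b, path)
  back <- parseStructure(path)
  expect_equal(nResidues(back), nResidues(b))
  expect_equal(caCoords(back), round(caCoords(b), 3), tolerance = 1e-6)
  expect_equal(residueLetters(back), residueLetters(b))
  expect_equal(confidences(back), confidences(b))
})

test_that("trimLowConfidence drops residues below the cutoff, keeping numbering", {
  m <- structureModel("t", matrix(rnorm(30), 10, 3),
                      confidence = rep(c(90, 50), 5))
  tr <- trimLowConfidence(m, 70)
  expect_equal(nResidues(tr), 5L)
  expect_equal(residueIndices(tr), seq(1L, 9L, 2L))
  expect_equal(nResidues(trimLowConfidence(m, 0)), 10L)
  all30 <- structureModel("low", matrix(rnorm(30), 10, 3),
                          confidence = rep(30, 10))
  expect_equal(nResidues(trimLowConfidence(all30, 70)), 0L)
  noconf <- structureModel("nc", matrix(rnorm(30), 10, 3))
  expect_warning(out <- trimLowConfidence(noconf, 70), "no confidence")
  expect_equal(nResidues(out), 10L)
})

test_that("kabsch recovers exact rigid transforms", {
  set.seed(41)
  P <- matrix(rnorm(45), 15, 3)
  f <- kabsch(P, sweep(P, 2, c(1, 2, 3), "+"))
  expect_equal(f$rmsd, 0, tolerance = 1e-10)
  expect_equal(f$translation, c(1, 2, 3), tolerance = 1e-10)
  expect_equal(f$rotation, diag(3), tolerance = 1e-10)
  for (case in 1:20) {
    R <- random_rotation()
    t <- rnorm(3, sd = 10)
    Q <- sweep(P %*% R, 2, t, "+")
    f <- kabsch(P, Q)
    expect_equal(f$rmsd, 0, tolerance = 1e-8)
    expect_equal(f$rotation, R, tolerance = 1e-8)
  }
  expect_error(kabsch(P, P[1:10, ]))
})

test_that("kabsch is optimal against a Monte-Carlo bound and stays proper", {
  set.seed(42)
  for (case in 1:20) {
    n <- sample(5:15, 1)
    P <- matrix(rnorm(3 * n), n, 3)
    Q <- matrix(rnorm(3 * n), n, 3)
    f <- kabsch(P, Q)
    expect_lte(f$rmsd, mc_min_rmsd(P, Q, 2000L) + 1e-9)
    expect_equal(crossprod(f$rotation), diag(3), tolerance = 1e-8)
    expect_equal(det(f$rotation), 1, tolerance = 1e-8)
  }
})

test_that("reflections are suppressed: a chiral mirror image keeps RMSD > 0", {
  P <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 2, 0), c(0, 0, 1))
  Q <- P; Q[, 1] <- -Q[, 1]          # mirror image
  f <- kabsch(P, Q)
  expect_gt(f$rmsd, 0.1)
  # reflection-allowed optimum is 0: verify the mirror really is congruent
  expect_equal(as.numeric(dist(P)), as.numeric(dist(Q)), tolerance = 1e-12)
})

test_that("kabsch RMSD is invariant under proper rigid pre-transforms", {
  set.seed(43)
  P <- matrix(rnorm(60), 20, 3)
  Q <- matrix(rnorm(60), 20, 3)
  base <- kabsch(P, Q)$rmsd
  for (case in 1:5) {
    R <- random_rotation(); t <- rnorm(3, sd = 20)
    expect_equal(kabsch(sweep(P %*% R, 2, t, "+"), Q)$rmsd, base,
                 tolerance = 1e-8)
    expect_equal(kabsch(P, sweep(Q %*% R, 2, t, "+"))$rmsd, base,
                 tolerance = 1e-8)
  }
})

test_that("tmD0 follows the standard length scale with its clamp", {
  expect_equal(tmD0(120), 1.24 * 105^(1/3) - 1.8, tolerance = 1e-12)
  expect_equal(tmD0(120), 4.05, tolerance = 0.01)
  expect_equal(tmD0(21), 0.5)
  expect_equal(tmD0(5), 0.5)
  L <- 22:400
  expect_true(all(diff(tmD0(L)) > 0))
})

test_that("tmScore is 1 for self, bounded in (0,1], and matches the noise oracle", {
  b <- makeHelicalBundle(8, 22, seed = 12)   # 204 residues
  n <- nResidues(b)
  pairs <- cbind(1:n, 1:n)
  expect_equal(tmScore(pairs, caCoords(b), caCoords(b), n), 1.0)

  # analytic oracle: with iid Gaussian noise (sd sigma per axis), d^2 ~
  # sigma^2 * chisq(3); E[1/(1+(d/d0)^2)] by numerical integration
  sigma <- 0.5
  d0 <- tmD0(n)
  expected <- stats::integrate(function(x)
    1 / (1 + sigma^2 * x / d0^2) * stats::dchisq(x, df = 3), 0, Inf)$value
  noisy <- perturbStructure(b, sigma, seed = 77)
  got <- tmScore(pairs, caCoords(noisy), caCoords(b), n)
  expect_equal(got, expected, tolerance = 0.02)
  expect_gt(got, 0); expect_lte(got, 1)
})

test_that("structureAlign of a model with itself is exact and deterministic", {
  b <- makeHelicalBundle(4, 25, seed = 3)
  s <- structureAlign(b, b)
  expect_equal(tmScoreOf(s), 1.0)
  expect_equal(rmsdOf(s), 0, tolerance = 1e-8)
  expect_equal(alignedPairs(s)[, 1], alignedPairs(s)[, 2])
  s2 <- structureAlign(b, b)
  expect_identical(alignedPairs(s), alignedPairs(s2))
})

test_that("structureAlign recovers a planted terminal deletion offset", {
  b <- makeHelicalBundle(4, 25, seed = 8)
  xyz <- caCoords(b)
  trunc <- structureModel("trunc", xyz[-(1:10), , drop = FALSE],
                          aa = residueLetters(b)[-(1:10)])
  s <- structureAlign(trunc, b)
  p <- alignedPairs(s)
  expect_gt(mean(p[, 2] - p[, 1] == 10), 0.9)
  expect_gt(tmScoreOf(s), 0.85)
})

test_that("fold mismatch scores far below the same-fold threshold", {
  b <- makeHelicalBundle(4, 25, seed = 9)
  e <- makeExtendedChain(nResidues(b), seed = 10)
  s <- structureAlign(e, b)
  expect_lt(tmScoreOf(s), 0.3)
})

test_that("TM-score decreases monotonically with planted noise", {
  b <- makeHelicalBundle(4, 25, seed = 2)
  tms <- vapply(c(0.25, 0.5, 1, 2, 4), function(sg)
    tmScoreOf(structureAlign(perturbStructure(b, sg, seed = 5), b)),
    numeric(1))
  expect_true(all(diff(tms) < 0))
  expect_true(all(tms > 0 & tms <= 1))
})

test_that("screenByStructure passes same-fold candidates and rejects decoys", {
  refs <- fixtureReferences(42L)$refStructures
  cand <- refs[[1]]
  res <- screenByStructure(cand, refs)
  expect_true(attr(res, "pass"))
  expect_equal(names(res)[1], names(refs)[1])
  expect_equal(tmScoreOf(res[[1]]), 1.0)

  noisy <- perturbStructure(refs[[1]], 1.0, seed = 3)
  expect_true(attr(screenByStructure(noisy, refs), "pass"))

  decoy <- makeExtendedChain(120, seed = 4)
  expect_false(attr(screenByStructure(decoy, refs), "pass"))
})

test_that("all alignment rotations are orthonormal with det +1", {
  b <- makeHelicalBundle(4, 25, seed = 13)
  for (sg in c(0.5, 2)) {
    s <- structureAlign(perturbStructure(b, sg, seed = 6), b)
    R <- rotationMatrix(s)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
})
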