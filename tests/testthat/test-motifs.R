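sch <- defaultScheme()

# sparse structure whose residues are 10 A apart, so proximity sets are
# controlled exactly
sparse_model <- function(id, n = 12, spacing = 10) {
  structureModel(id, cbind(spacing * (seq_len(n) - 1), 0, 0),
                 aa = rep("A", n))
}

identity_sup <- function(lNorm, n) {
  new("Superposition", rotation = diag(3), translation = c(0, 0, 0),
      pairs = cbind(seq_len(n), seq_len(n)), rmsd = 0, tmScore = 1,
      lNorm = as.integer(lNorm))
}

test_that("mapProximalResidues under the identity returns the catalytic set", {
  m <- sparse_model("ref")
  catRef <- catalyticReference("ref", c(3L, 7L))
  got <- mapProximalResidues(m, m, identity_sup(12, 12), catRef, cutoff = 5)
  expect_equal(got$res_index, c(3L, 7L))
  expect_equal(got$min_distance, c(0, 0))
})

test_that("mapProximalResidues is invariant under the recorded transform", {
  m <- sparse_model("ref")
  shifted <- structureModel("cand", sweep(caCoords(m), 2, c(100, 0, 0), "+"),
                            aa = residueLetters(m))
  sup <- new("Superposition", rotation = diag(3),
             translation = c(-100, 0, 0),
             pairs = cbind(1:12, 1:12), rmsd = 0, tmScore = 1, lNorm = 12L)
  catRef <- catalyticReference("ref", c(3L, 7L))
  got <- mapProximalResidues(shifted, m, sup, catRef, cutoff = 5)
  expect_equal(got$res_index, c(3L, 7L))
  expect_equal(got$min_distance, c(0, 0), tolerance = 1e-10)
})

test_that("the proximity cutoff is a closed bound", {
  ref <- structureModel("ref", rbind(c(0, 0, 0)), aa = "D")
  cand <- structureModel("cand", rbind(c(4.9, 0, 0), c(5.1, 0, 0)),
                         aa = c("K", "R"))
  sup <- new("Superposition", rotation = diag(3), translation = c(0, 0, 0),
             pairs = cbind(1L, 1L), rmsd = 0, tmScore = 1, lNorm = 1L)
  catRef <- catalyticReference("ref", 1L)
  got <- mapProximalResidues(cand, ref, sup, catRef, cutoff = 5.0)
  expect_equal(got$res_index, 1L)
  expect_equal(got$aa, "K")
})

test_that("missing catalytic residues raise a named error", {
  m <- sparse_model("ref", 5)
  expect_error(
    mapProximalResidues(m, m, identity_sup(5, 5),
                        catalyticReference("ref", c(2L, 99L)), 5),
    "99")
})

test_that("extractMotifs reproduces the class ID motif strings", {
  expect_equal(extractMotifs(data.frame(res_index = c(95L, 96L),
                                        aa = c("D", "N")))$pattern, "DN")
  expect_equal(extractMotifs(data.frame(res_index = c(289L, 290L),
                                        aa = c("N", "D")))$pattern, "ND")
  expect_equal(extractMotifs(data.frame(res_index = c(338L, 341L, 342L),
                                        aa = c("R", "K", "D")))$pattern,
               "RXXKD")
  # all seven proposed catalytic residues in one call give the three motifs
  seven <- data.frame(res_index = c(95L, 96L, 289L, 290L, 338L, 341L, 342L),
                      aa = c("D", "N", "N", "D", "R", "K", "D"))
  expect_equal(extractMotifs(seven)$pattern, c("DN", "ND", "RXXKD"))
})

test_that("gaps beyond the merge rule split motifs", {
  far <- data.frame(res_index = c(10L, 20L), aa = c("D", "D"))
  expect_equal(extractMotifs(far, maxGap = 3)$pattern, c("D", "D"))
  close <- data.frame(res_index = c(10L, 14L), aa = c("D", "D"))
  expect_equal(extractMotifs(close, maxGap = 3)$pattern, "DXXXD")
  expect_equal(nrow(extractMotifs(data.frame(res_index = integer(),
                                             aa = character()))), 0L)
})

test_that("motif round trip: patterns re-render the listed residues", {
  set.seed(81)
  for (case in 1:20) {
    idx <- sort(sample(1:60, sample(2:6, 1)))
    aa <- sample(c("D", "N", "R", "K", "E"), length(idx), replace = TRUE)
    mot <- extractMotifs(data.frame(res_index = idx, aa = aa))
    for (r in seq_len(nrow(mot))) {
      pat <- strsplit(mot$pattern[r], "")[[1]]
      expect_equal(length(pat), mot$end[r] - mot$start[r] + 1L)
      pos <- mot$positions[[r]]
      expect_equal(pat[pos - mot$start[r] + 1L],
                   aa[match(pos, idx)])
      expect_true(all(pat[-(pos - mot$start[r] + 1L)] == "X"))
    }
  }
})

test_that("starMsa projects homologs onto anchor columns", {
  anchor <- "MKLAVDEWRHG"
  same <- c(h1 = anchor, h2 = anchor)
  msa <- starMsa(anchor, same, sch)
  expect_equal(dim(msa), c(2L, nchar(anchor)))
  expect_true(all(msa[1, ] == strsplit(anchor, "")[[1]]))

  # a deletion leaves one gap at the deleted anchor column
  del <- c(d1 = paste0(substr(anchor, 1, 4), substr(anchor, 6, 11)))
  msaD <- starMsa(anchor, del, sch)
  expect_equal(sum(msaD == "-"), 1L)

  # an insertion is invisible after projection
  ins <- c(i1 = paste0(substr(anchor, 1, 5), "GGG", substr(anchor, 6, 11)))
  msaI <- starMsa(anchor, ins, sch)
  expect_equal(ncol(msaI), nchar(anchor))
  expect_equal(paste(msaI[1, ], collapse = ""), anchor)
})

test_that("column information content matches direct entropy evaluation", {
  msa <- rbind(rep("D", 20), matrix("D", 19, 20))   # invariant columns
  cons <- columnConservation(msa)
  expect_equal(cons$ic, rep(log2(20), 20))
  expect_equal(unname(cons$heights["D", 1]), log2(20))

  # uniform column: each letter once
  uni <- matrix(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"), 20, 1)
  expect_equal(columnConservation(uni)$ic, 0)

  # 18 D + 2 N: IC = log2(20) - H(0.9, 0.1)
  col <- matrix(c(rep("D", 18), rep("N", 2)), 20, 1)
  H <- -(0.9 * log2(0.9) + 0.1 * log2(0.1))
  expect_equal(columnConservation(col)$ic, log2(20) - H)

  # all-gap column
  expect_equal(columnConservation(matrix("-", 5, 1))$ic, 0)
})

test_that("IC is bounded and heights sum to IC on random alignments", {
  set.seed(82)
  for (case in 1:20) {
    msa <- matrix(sample(c("A", "D", "N", "R", "K", "-"), 120, replace = TRUE),
                  12, 10)
    cons <- columnConservation(msa)
    expect_true(all(cons$ic >= 0 - 1e-12))
    expect_true(all(cons$ic <= log2(20) + 1e-12))
    expect_equal(colSums(cons$heights), cons$ic)
  }
})

test_that("motifConsensus writes alternation groups for mixed columns", {
  # column 1: all D; column 2: 12 N + 8 D -> majority letter first
  msa <- rbind(matrix(c("D", "N"), 12, 2, byrow = TRUE),
               matrix(c("D", "D"), 8, 2, byrow = TRUE))
  expect_equal(motifConsensus(msa, 1:2), "D(N/D)")
  scattered <- matrix(sample(c("A", "C", "G", "T", "W", "Y", "M", "K"), 40,
                             replace = TRUE), 40, 1)
  expect_true(grepl("X|\\(", motifConsensus(scattered, 1)))
})
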