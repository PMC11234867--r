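---
title: "Mining genomes for non-canonical terpene synthases by structure similarity"
author: "tpsmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining genomes for non-canonical terpene synthases by structure similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Motivation and model

Terpene synthases (TPSs) cyclize linear prenyl diphosphates (FPP, GGPP,
GFPP) into terpene skeletons. Class I enzymes initiate catalysis by
Mg²⁺-assisted diphosphate elimination and are recognized in sequence by
the DDXXD and NSE/DTE motifs; class II enzymes use DXDD. *Non-canonical*
TPSs carry none of these signatures, so motif- or homology-based genome
mining cannot see them — but several characterized examples still adopt a
class I-like α-helical fold, and their catalytic residues occupy the same
spatial positions as the canonical motifs. `tpsmine` operationalizes that
observation: a candidate is interesting when its *predicted structure*
matches a reference TPS fold even though its *sequence* matches nothing.

The pipeline composes four filters (each one only removes candidates, so
stage counts are monotone):

1. **Anchor windowing.** TPS substrates are made by *E*-isoprenyl
   diphosphate synthases (E-IDS). Genes encoding proteins similar to a
   user-supplied E-IDS reference set (E < `anchorEMax`, default 10⁻⁵)
   become anchors, and all protein-coding genes within ±`windowK` genes
   (default 10) on the same contig are collected. Offsets are counted in
   genes, not base pairs, over CDS features only; windows truncate at
   contig ends and never cross contigs. Setting `windowK = Inf` disables
   the window for cluster-independent searches, at the cost of a much
   larger candidate pool.
2. **Hypothetical-annotation filter.** Products matching
   "hypothetical", "uncharacterized", "unknown function" or "DUF"
   (case-insensitive), or empty product strings, are kept. Annotation
   strings are taken at face value.
3. **Structure screen.** Each candidate's Cα model is trimmed at
   pLDDT ≥ `plddtMin` (default 70) and aligned, without any sequence
   prior, to each reference TPS structure; the candidate passes when its
   best TM-score reaches `tmMin` (default 0.5, the conventional same-fold
   threshold). Candidates without a model file are skipped with a log
   line rather than an error, mirroring mining runs restricted to
   proteins with available predicted models.
4. **Known-TPS exclusion.** Candidates whose best hit against a known-TPS
   sequence set has E < `knownTpsEMax` (default 10⁻⁵) are removed — such
   proteins are discoverable by ordinary homology search and are not the
   target of this workflow. The threshold for this step is not fixed by
   precedent; 10⁻⁵ was chosen to match the homolog-census cutoff and is
   configurable.

Survivors are clustered into **types** and annotated with **active-site
motifs** (below).

## Sequence statistics

Local alignment is exact Smith–Waterman dynamic programming (no seeding
heuristics — candidate sets are small enough that correctness beats
speed), computed through `Biostrings::pairwiseAlignment` with BLOSUM62,
gap open 11 and gap extend 1, a gap of length *g* costing 11 + *g*.
`X` is score-neutral (0 against everything, including itself). Raw scores
convert to E-values by the Karlin–Altschul model

$$E = K\,m\,n\,e^{-\lambda S},$$

with the standard gapped constants λ = 0.267 nats, K = 0.041 for this
matrix/penalty combination; *n* is the total residue count of the searched
database. No composition-based statistics and no effective-length (edge)
correction are applied; users who need BLAST-identical numbers should
tighten thresholds accordingly, as the uncorrected E-values here are
slightly conservative for short sequences.

**Typing.** The pairwise E-value of two candidates is the smaller of the
two directional values (they coincide when both sequences form the whole
database, but the minimum is kept as the documented, conservative
convention). Types are the connected components of the graph with edges
at E < `typeEMax` (default 0.1) — single linkage, the weakest clustering
assumption consistent with the notion of mutually similar "types".
Clusters are labelled `type-1`, `type-2`, … by decreasing size, ties
broken by smallest member id, so runs are reproducible. Note that at
E < 0.1 roughly one random pair in ten forms a spurious edge by
construction of the E-value; types are therefore coarse by design, and a
stricter threshold can be passed when finer partitions are wanted.

## Structure comparison

All comparison is Cα-only: predicted-model confidence is per-residue, and
side chains add noise and cost without changing fold-level decisions.

**Kabsch superposition.** The optimal rigid transform minimizing RMSD is
the SVD solution with the smallest singular direction sign-corrected so
the rotation is always proper (det +1): mirror-image folds keep a
positive RMSD.

**TM-score.** With aligned pairs at distances $d_i$ and normalization
length $L$ (the reference length),

$$\mathrm{TM} = \max \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0(L))^2},
\qquad d_0(L) = 1.24\,(L-15)^{1/3} - 1.8\ \text{Å},$$

clamped at 0.5 Å for L ≤ 21. The maximum is taken over superpositions
fitted on the iteratively re-selected subset of pairs closer than
$d_0$ (the standard superpose–score–reselect protocol, best score kept).

**Sequence-independent alignment.** Initial pairings come from gapless
threadings of the mobile onto the reference at every offset with stride
5, plus an N-terminal 30-mer seed. Each seed is refined by iterating:
Kabsch fit on the current pairs → similarity matrix
$S_{ij} = 1/(1+(d_{ij}/d_0)^2)$ → global dynamic programming with a flat
gap penalty of 0.6 (no extension term; ties broken
diagonal-then-up-then-left in compiled code) → new pairs, until the pair
set repeats or 30 iterations. The seed with the highest TM-score wins;
the algorithm is deterministic for fixed inputs. The reported RMSD is the
least-squares optimum over the *final aligned pair set* (not all
residues), which is how domain-vs-domain RMSDs are conventionally quoted;
comparisons with other tools should expect protocol-level differences of
a few tenths of an Å.

## Active-site motifs and conservation

Catalytic residues of each reference structure are declared in a
`catalyticReference` table. After superposition, candidate residues whose
transformed Cα lies within `proximityCutoff` of any catalytic Cα are
reported ("sterically close"; 5.0 Å, a closed bound, approximates
side-chain contact range — the atom selection underlying published
proximity statements is generally not stated, so the cutoff is
configurable). Proximal residues whose indices differ by at most
`maxGap + 1` (default gap 3) merge into one motif string with interior
unlisted positions rendered as `X`, e.g. residues {338:R, 341:K, 342:D}
→ `RXXKD`.

Cross-homolog conservation uses a star alignment: every homolog is
globally aligned to the anchor and projected onto the anchor's columns
(insertions relative to the anchor are dropped). Column information
content is IC = log₂20 − H over the 20 canonical letters of the non-gap
symbols (gaps and X excluded; no small-sample correction by default —
the simplest defensible estimator, with an optional pseudocount). Letter
heights (frequency × IC) export as a TSV consumable by standard logo
plotters. Alternation groups such as `(N/D)` are produced only at this
cross-homolog stage, when the top two letters jointly reach 80%
frequency — a single sequence never yields an alternation.

## Phylogeny

Homolog distances are d = 1 − alignment identity (identical positions
over alignment length including gaps), clamped to [0, 1], with d = 1 for
pairs lacking any positive-scoring alignment; a Kimura multiple-hit
correction is available but off by default since the tree is
illustrative, not the inference target. Trees are neighbor joining
(`ape::nj`) with negative branch lengths clamped to zero and the deficit
moved to the sibling edge, preserving path lengths through the parent;
on additive matrices the generating topology and branch lengths are
recovered exactly. Newick output carries 6-decimal branch lengths and
single-quotes labels containing spaces or structural characters. No
bootstrap values are attached by default.

## The synthetic-fixture generator

Every stage is testable offline because `makeSyntheticGenome` builds
inputs with known ground truth:

* **Structures** are idealized Cα geometry: α-helices with 1.5 Å rise and
  100° twist per residue on a 2.3 Å radius, packed antiparallel on an
  8 Å circle with 4-residue loops (`makeHelicalBundle`); decoys are
  extended 3.8 Å-spaced zigzag chains. `perturbStructure` adds isotropic
  Gaussian noise (per-axis σ) followed by a random proper rigid
  transform, so superposed RMSD concentrates at σ√3.
* **Families** come from `mutateProtein`, which substitutes a
  Bernoulli(1 − identity) fraction of positions with BLOSUM-positive
  replacements, keeping mutants detectable as homologs.
* **Genomes** plant, per contig of 28 CDS: one anchor (a 70%-identity
  copy of the E-IDS reference, near the contig middle), one true
  candidate (hypothetical-annotated, 3 genes downstream, structure = the
  class I reference bundle at σ = 1.0 Å), one known-TPS decoy
  (hypothetical-annotated and fold-similar, but sequence-similar to the
  known-TPS set, so that only the exclusion filter rejects it), one
  hypothetical protein outside the window with an extended-chain
  structure, and otherwise unrelated genes with informative product
  annotations. Coding sequences are reverse-translated with random
  synonymous codons under genetic code 11 (every fixture protein starts
  with M so translations round-trip the initiator convention); strands
  and intergenic spacers are random. Sequence and structure are generated
  independently except where similarity is planted — the pipeline never
  predicts structure, so consistency between a gene's sequence and its
  model is unnecessary.

These sizes are chosen so a full 20-genome recovery run plus all oracle
checks completes in a few minutes on one CPU: genomes of 28 genes with
150–350-residue proteins, 112-residue reference bundles, alignment-oracle
sequences of length ≤ 8 (where exhaustive enumeration is feasible), 100
point clouds vs 10,000 random transforms, 50 random 5–12-taxon trees.

What passing these tests does **not** show about real data: fixture
sequences are compositionally uniform (no low-complexity or repeat
regions that inflate local-alignment scores), annotations are clean and
consistent, structures are ideal geometry rather than predicted models
with correlated error, and the planted similarity structure is far
cleaner than homology in nature. The fixtures validate the machinery,
not the biological discovery rate.

## Degenerate inputs and edge behavior

Empty candidate sets flow through every stage and produce an empty,
well-formed report (exit 0 at the command line). CDS with unresolvable
locations (trans-record joins, mixed-strand joins) are skipped with a
warning; fuzzy coordinates (`<`, `>`) are truncated with a warning.
Ambiguous codons that resolve to a unique amino acid are translated,
others become X; translation stops at the first stop codon. Structure
models need ≥ 20 residues after confidence trimming, superpositions ≥ 3
points; models with no confidence values pass through trimming unchanged
with a warning. All-gap alignment columns get IC 0. Re-running any
configuration reproduces byte-identical reports: every ordering in the
pipeline is fully specified, and all randomness in the fixture generator
flows from explicit seeds.

## Known limitations

* E-values lack composition and edge corrections (documented above).
* The structure aligner is rigid-body only — no flexible or hinge
  alignment — and its threading-seed protocol, while deterministic, is
  not guaranteed to find the global TM-score optimum for very dissimilar
  topologies (where scores are far below threshold anyway).
* "Hypothetical" status is read from annotation strings; pipelines run on
  re-annotated genomes will see different candidate pools.
* Homolog counts depend on the searched database release and are not
  comparable across databases.
* Fetching genomes or predicted models from remote services is out of
  scope: all inputs are local paths.

## A minimal run

```{r example}
library(tpsmine)
coll <- makeFixtureCollection(tempfile("fx"), nGenomes = 2, seed = 11)
report <- runMining(coll$config)
candidateTable(report)
census <- runHomologCensus(report, someProteinFasta, coll$config)
```
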