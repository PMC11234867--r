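# tpsmine

Structural-model-based genome mining of non-canonical terpene synthases
(TPSs), for R.

Canonical class I TPSs are found by sequence homology against their
conserved active-site motifs (DDXXD, NSE/DTE). Non-canonical TPSs have
primary sequences that look like nothing known — yet their predicted 3D
folds still resemble class I enzymes. `tpsmine` implements a mining
workflow that exploits this: it screens **hypothetical proteins near an
anchor gene by structure similarity instead of sequence similarity**, so
candidates invisible to BLAST- or HMM-style searches become discoverable.
The intended users are natural-product and enzyme-discovery groups working
from annotated genomes plus per-protein structure models (e.g. AlphaFold DB
files).

## The workflow

For each genome the pipeline applies four filters, in order:

1. **Anchor neighborhood** — find *E*-isoprenyl diphosphate synthase
   (E-IDS) genes, which make the prenyl diphosphate substrate of TPSs, by
   local alignment against a reference set, and collect all genes within
   ±k genes of each anchor (k = 10 by default; k = ∞ disables the window).
2. **Hypothetical annotation** — keep genes whose product strings mark them
   as uncharacterized ("hypothetical", "uncharacterized", "unknown
   function", "DUF…", or empty).
3. **Structure screen** — align each candidate's Cα model (pLDDT-trimmed at
   70) against reference class I / IB / IC TPS structures without any
   sequence prior, and keep candidates whose best TM-score ≥ 0.5, the
   conventional same-fold criterion.
4. **Known-TPS exclusion** — drop candidates whose sequences resemble known
   TPSs (E < 10⁻⁵), since those are reachable by ordinary homology search.

Survivors are clustered into **types** (single-linkage components of the
pairwise E < 0.1 graph), their residues sterically close to the reference
catalytic site are compressed into **active-site motif strings** (e.g.
`RXXKD`), and homolog sets can be counted and placed on a neighbor-joining
tree.

## Statistics and numerics

* Local alignment is exact Smith–Waterman under BLOSUM62 with affine gaps
  (open 11, extend 1); significance uses the Karlin–Altschul model
  *E* = *K·m·n·e^(−λS)* with the standard gapped constants λ = 0.267,
  *K* = 0.041 (bit score (λS − ln K)/ln 2).
* Superposition is Kabsch's SVD solution restricted to proper rotations
  (det +1), so mirror images are never matched.
* Structure similarity is the TM-score,
  TM = max (1/L) Σᵢ 1/(1 + (dᵢ/d₀(L))²) with
  d₀(L) = 1.24·(L−15)^⅓ − 1.8 Å (clamped at 0.5 Å), normalized by the
  reference length, maximized by the standard iterative
  superpose–score–realign protocol over gapless threading seeds.
* Sequence-independent alignment iterates {Kabsch fit → similarity matrix
  Sᵢⱼ = 1/(1+(dᵢⱼ/d₀)²) → global dynamic programming (flat gap −0.6)} to
  convergence.
* Conservation logos use per-column information content
  IC = log₂20 − H over non-gap residues; letter heights are frequency × IC.
* Trees are neighbor joining on d = 1 − alignment identity, with negative
  branch lengths clamped to zero (deficit moved to the sibling edge).

Everything is testable offline: the `synthetic_fixtures` generator builds
genomes (GenBank), protein families and Cα models (PDB) with planted ground
truth.

## Worked example

```r
library(tpsmine)

# two synthetic genomes, each planting one anchor, one true candidate,
# one known-TPS decoy and one out-of-window hypothetical protein
coll   <- makeFixtureCollection("example-fixtures", nGenomes = 2, seed = 11)
report <- runMining(coll$config)
report
#> CandidateReport: 2 candidate(s)
#>   stage counts: window=40 -> hypothetical=4 -> structure=4 -> known_tps=2
#>   1 type(s)

candidateTable(report)[, c("gene_id", "offset", "best_ref", "tm_score",
                           "rmsd", "type", "motifs")]
#>         gene_id offset   best_ref  tm_score     rmsd   type
#> 1 syng11001_g17      3 classI-syn 0.8936216 1.647374 type-1
#> 2 syng11002_g17      3 classI-syn 0.8891150 1.682610 type-1
#>                                     motifs
#> 1 RXWDDXA,KNHK,LXHKR,KXXTKPHL,LKDGD,EXMPAH
#> 2   WDDXATXXE,QXNHKXQ,KR,TKPXL,EXLKD,REFMP
```

Reading the output: 40 genes fell inside the two anchor windows; 4 were
annotated hypothetical; all 4 had TPS-like folds (TM ≈ 0.89 against the
class I reference, RMSD ≈ 1.7 Å); the 2 known-TPS decoys were removed by
the sequence filter. The two surviving candidates — exactly the planted
ones — are mutually similar (one type) and their residues within 5 Å of
the reference catalytic site compress into short motif strings.

The same machinery is scriptable from a shell via `exec/tpsmine`
(`mine`, `census`, `fixtures make`, `align-structures`, `logo`).

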