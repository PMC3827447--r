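# diplophylo

Phylogenomic supermatrix curation and ordinal-level phylogenetics for
millipede (Diplopoda) transcriptome data.

## The problem

Ordinal-level millipede phylogeny has long been contested: morphological
character systems (gonopods, ozopores, spinnerets) conflict across
classifications, and earlier molecular studies lacked loci or taxa.
Transcriptome sequencing yields hundreds of nuclear protein-coding
orthologs per exemplar, but raw ortholog alignments are riddled with
paralogous sequences, ambiguous leading residues, misaligned indel-rich
segments and fragments. `diplophylo` provides the full chain from reads
to inference-ready matrix and downstream comparative analyses, for anyone
assembling amino-acid supermatrices from per-locus transcriptome
orthologs:

* **readqc** — FASTX-style paired-end trimming (truncate after the first
  base with Phred ≤ 20, drop reads < 30 bases, strip 9 head bases) with
  pair resynchronization.
* **curation** — per-locus hygiene: leading-`X` masking in the first 20
  positions; plurality-consensus divergence filtering (a sequence whose
  residues differ from the consensus at ≥ 75% of comparable columns is
  deleted as putative paralog); all-gap/singleton column deletion;
  chimeric representative selection; ≥ 100-residue, ≥ 100-column,
  ≥ 11-taxon filters.
* **trimming** — a re-implementation of classic conserved-block selection
  (b1 = b2 = ⌊n/2⌋+1, b3 = 8, b4 = 10, gap rule "half") plus Monte-Carlo
  sliding-window masking of low-signal columns.
* **supermatrix** — concatenation with partition table and every
  composition statistic: gap/missing percentages over *N*·*L* cells,
  per-taxon locus inclusion, CEG coverage summaries, reduction reports.
* **asr** — Fitch parsimony for discrete unordered characters. Downpass
  sets by the classic algorithm; final sets are exact MPR sets (states a
  node takes in at least one most-parsimonious reconstruction), computed
  by unit-cost dynamic programming and cross-checked by exhaustive
  enumeration.
* **phylolik** — Felsenstein pruning for amino acids (WAG or Poisson,
  discrete-gamma rates, per-node rescaling) with coordinate-wise Brent
  branch-length optimization; emits CONSEL-style site log-likelihoods.
* **topotest** — the RELL test battery on a site log-likelihood matrix:
  KH, SH and weighted variants from centered replicates, bootstrap
  proportions, posterior probabilities, and the AU test via multiscale
  bootstrap with a weighted probit fit of
  p(s) = Φ(−d·√s − c/√s), reported as p(AU) = Φ(−d + c).
* **synthdata / cli** — a labeled-defect synthetic ortholog generator
  matching the study conditions (12 taxa, 1005 loci, published per-taxon
  recovery levels) and `run_pipeline()` for seeded end-to-end runs with
  exact sequence accounting.

## Worked example

```r
library(diplophylo)

## composition statistics from the optimized 221-locus matrix dimensions
post <- stats_from_counts(n_loci = 221, n_columns = 61641, n_taxa = 12,
                          n_gap = 53286, n_missing = 75146)
print(post)
#> matrix_stats: 221 loci, 61641 columns, 12 taxa
#>   gaps    53286 (7.20%)
#>   missing 75146 (10.16%)

## parsimony history of spinnerets on the reference topology
res <- fitch(millipede_topology(), millipede_characters()$spinnerets)
print(res)
#> parsimony reconstruction of 'spinnerets': score 2 (min changes)
cl <- millipede_clades()
asr_states(res, cl$Eugnatha)    # 1 : spinnerets at the Eugnatha ancestor
asr_states(res, cl$Juliformia)  # 0 : subsequently lost in the Juliformia
```

The two printed percentages are the gap and missing-data content of the
optimized supermatrix (denominator 12 × 61,641 cells). The spinneret
reconstruction needs two changes — one gain on the Eugnatha stem, one
loss on the Juliformia stem — which is why spinnerets are a doubtful
diagnostic for the traditional Nematophora.

A seeded end-to-end run on synthetic data:

```r
cfg <- pipeline_config(sim = sim_config(n_loci = 50, seed = 1),
                       out_dir = "run1", seed = 11)
res <- run_pipeline(cfg)
res$manifest    # per-stage sequence accounting; always balances exactly
```

A thin command-line wrapper with the usual subcommands (`simulate`,
`readqc`, `curate`, `asr`, `topotest`, `run-all`, ...) is installed at
`inst/scripts/diplophylo.R`.

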