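---
title: "Methods: supermatrix curation, ancestral states and topology tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supermatrix curation, ancestral states and topology tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope and model of the data

`diplophylo` re-implements, as tested and reusable functions, the analysis
chain used for ordinal-level millipede phylogenomics from transcriptome
data: paired-end read quality control, per-locus ortholog alignment
curation, conserved-block selection and low-signal masking, concatenation
into a partitioned amino-acid supermatrix with complete composition
statistics, Fitch parsimony ancestral-state reconstruction of three
morphological characters (gonopods, ozopores, spinnerets), an amino-acid
pruning likelihood engine, and the RELL-based topology test battery (AU,
NP, BP, PP, KH, SH, WKH, WSH).

The data model is deliberately simple: a per-locus alignment is a character
matrix over the 20 amino acids plus `X` (ambiguous) and `-` (gap); a
supermatrix additionally uses `?` for taxa absent from a locus. In all
composition statistics, `-` counts as a gap while `?` and `X` count as
missing, and percentages use the full `taxa x columns` cell count as
denominator. This convention is validated by reproducing the published
values 7.20% / 10.16% (post-optimization gaps and missing), 28.02% /
28.73% (pre-optimization), the 11.59% size retention and the 20.82 /
18.57-point reductions exactly from the printed counts.

# Read quality control

`process_pairs()` applies, per read and in sentence order: truncation at
the first base with Phred quality at or below `q_threshold` (default 20;
the triggering base is *kept*, reading "all sites occurring after"
literally -- the opposite convention is a one-line change in
`quality_truncate()`), deletion of reads shorter than `min_len` (default
30 bases), removal of the first `head_trim` bases (default 9), and pair
resynchronization (both mates must survive). The length filter runs
*before* head trimming even though trimming can leave shorter reads; that
ordering follows the upstream protocol being reproduced. Input qualities
are assumed Sanger/Illumina-1.8 (+33), configurable via `phred_offset`.

# Per-locus curation

The cascade runs in a fixed order: leading-ambiguity masking -> locus
selection -> block selection -> uninformative-column deletion ->
consensus-divergence filtering -> low-signal masking -> length/occupancy
filtering. Choices where the upstream tools are under-specified:

* **Leading ambiguity** (`trim_leading_ambiguity()`): everything from
  position 1 through the last `X` inside the first 20 alignment positions
  is replaced by gaps. Working alignment-safe (replacing rather than
  deleting) generalizes the original pre-alignment trimming script without
  breaking column geometry.
* **Consensus** (`consensus()`): per-column plurality of non-gap
  residues, ties broken alphabetically, all-gap columns yield `-`. The
  upstream tool names only "the consensus"; fixing plurality plus an
  alphabetical tie-break makes the filter deterministic.
* **Divergence** (`remove_divergent()`): mismatches over *comparable*
  columns -- those where both the sequence and the consensus hold a
  residue. Counting gapped columns as mismatches would delete legitimately
  short sequences that the length filter already handles. Sequences at or
  above the 0.75 threshold are deleted in a single pass against the
  original consensus (no recomputation between removals); an all-gap
  sequence has no comparable columns and is removed. On labeled synthetic
  paralogs redrawn at 90% of their residue positions the filter removes
  100%, and it removes 0% of sequences constructed at divergence 0.5 or
  below; both properties are asserted by the test suite.
* **Representative selection** (`representative_per_taxon()`):
  non-overlapping fragments of one taxon are merged into a chimera; of
  overlapping copies, the one with the most non-gap residues is kept (tie:
  alphabetically first id). Together with the per-locus missing-data
  ceiling (50% of cells) this approximates the chimera/locus-selection
  stage of the original pipeline; the full set of its flags is not
  reproduced.
* **Length/occupancy** (`apply_length_and_occupancy()`): sequences under
  100 non-gap residues, then alignments under 100 columns, then
  alignments with fewer than 11 distinct taxa, then loci over the
  missing-data ceiling. The taxon cutoff is 11 with a 12-taxon working
  set; the source describes the same cutoff against both 12 and 13
  (counting the reference taxon *Daphnia* separately), so the denominator
  is configurable but the default follows the 12 included taxa.

# Block selection and masking

`select_blocks()` re-implements the classic conserved-block algorithm at
the study's settings: conservation thresholds `floor(n/2) + 1` for both
"conserved" and "highly conserved" (so the two classes coincide), maximum
nonconserved run 8, minimum block 10, and the "half" gap rule (a column is
gap-class when at least 50% of sequences are gapped). Steps run in a fixed
order -- long nonconserved runs, flank trimming to highly conserved
columns, gap columns plus adjacent nonconserved runs, minimum block length
-- and the kept-column set is verified against an independently coded
scan oracle on hundreds of random alignments.

`mask_low_signal()` is an explicitly approximate, Monte-Carlo
re-implementation of sliding-window randomness detection: per sequence
pair, window identity scores (+1 identical non-gap residues, -1 otherwise;
window 6) are compared against the 95th percentile of scores from 100
windows drawn from the pair's pooled residue composition; windows at or
below the null quantile vote their columns low-signal, and a column is
masked when more than half of the pairs vote it down. Identity scoring
keeps the null analytically checkable; the original tool's exact scoring
and defaults are not published, so exact reproduction is a non-goal.
Masked columns are deleted downstream. The window width, replicate count
and quantile were fixed once at these conventional values.

# Supermatrix statistics

`concatenate()` orders loci lexicographically (the original
concatenation order is unknown and irrelevant to every statistic), fills
absent taxa with `?`, and the conservation identity residues + gaps +
missing = taxa x columns is asserted on every `matrix_stats()` call.
Recomputed inclusion percentages are reported as computed; where a
published rounding disagrees at the second decimal the package reports
its own arithmetic.

# Ancestral states

`fitch()` reports classic downpass state sets (generalized over
polytomies by majority-intersection) and *exact* MPR sets computed by
unit-cost dynamic programming over subtree and outside costs. The DP also
yields the parsimony score and is exact on polytomies, where the
union-count shortcut is not defined; on binary trees the two agree, which
the test suite checks against exhaustive enumeration
(`enumerate_mprs()`, guarded to 12 tips / 4 states) on hundreds of random
instances. Outgroup tips are coded 0 for all three characters: ticks,
water fleas and centipedes lack millipede gonopods, ozopores and
spinnerets. The polydesmidan spinneret tip is coded present, following
reports of functional spinnerets in Polydesmida; the study matrix itself
was never printed, so tip codings are reconstructed from the state
definitions and the ordinal descriptions. On the reference topology the
reconstructions give: gonopods from leg pairs 9+10 at the Colobognatha
ancestor, 8+9 at the Eugnatha ancestor, and an ambiguous Helminthomorpha
ancestor -- the full MPR set there is {0, 1, 2}, since a gonopod-less
ancestor with two independent gains also attains the two-change minimum;
ozopores present from the Helminthomorpha ancestor throughout; spinnerets
present at the Eugnatha ancestor and all internal descendants except the
Juliformia.

# Likelihood engine

`site_logliks()` implements Felsenstein pruning with per-node
log-scaling (results are independent of the scaling scheme), WAG or
Poisson exchangeabilities, and equiprobable discrete-gamma categories
using category means (4 categories by default; shape fixed at 1 unless
estimation is enabled). WAG constants are taken from phangorn's published
model table. Transition probabilities come from the symmetrized
eigendecomposition of the normalized generator. Gaps, `?` and `X` are
fully missing (partial likelihood 1 for every state). Duplicate site
patterns are compressed once and shared across topologies.

`optimize_branch_lengths()` does coordinate-wise Brent search per branch
using inside/outside partials, so each trial length costs one
transition-matrix product; a new length is accepted only when the total
log-likelihood improves, making it nondecreasing across sweeps.
Convergence is declared when a sweep gains less than 1e-6 log units
(at most 20 sweeps); branch lengths are bounded in [1e-8, 10]. Under a
reversible model the two root-adjacent branch lengths are identifiable
only through their sum, and validation treats them accordingly. Parameter
recovery is checked on a 6-tip tree with 5,000 simulated WAG sites
(internal branches within 15% relative error).

# Topology tests

`run_battery()` consumes a site log-likelihood matrix. KH compares each
topology to the maximum-likelihood one via centered RELL replicate
differences (one-sided); SH uses the centered max-statistic over the
candidate set and is conservative relative to KH by construction (the
suite asserts `SH >= KH` for non-best topologies). The weighted variants
studentize the pairwise differences by their replicate standard
deviations; with a single fixed comparator the studentization cancels, so
WKH numerically tracks KH and both are reported for interface
completeness, while WSH genuinely differs from SH. BP is the strict
best-count proportion at scale 1; NP is the tie-split, add-half smoothed
version of the same proportion. PP normalizes exponentiated total
log-likelihoods. The AU test fits the two-parameter signed-distance /
curvature model `p(s) = Phi(-d sqrt(s) - c / sqrt(s))` to best-count
proportions across resample scales 0.5-1.4 by weighted least squares on
the probit scale with binomial-variance weights; scales with proportion
exactly 0 or 1 are dropped, and a fit with fewer than two usable scales
is clamped to 0/1 with a warning. Under an exchangeable null the
pairwise KH p-value is uniform; calibration is asserted over 1,000
simulated null datasets (type-I error within [0.03, 0.07] at alpha 0.05).

# Synthetic data

`simulate_ortholog_set()` generates the study conditions: 12 taxa, 1005
loci averaging ~529 aligned residues (gamma-distributed lengths, shape 8),
per-taxon recovery probabilities equal to the published pre-optimization
inclusion levels (the reference taxon always recovered, the EST taxon at
~0.17), per-column conservation drawn from Beta(5, 1) around a random
residue profile, and labeled defects: paralog replacement redrawn at 90%
of residue positions (so the 75% filter has true positives by
construction), leading `X` runs of 1-15 positions, indel-rich segments of
6-20 columns, and fragments of 30-99 residues. Defect rates default to
0.05 / 0.10 / 0.25 / 0.05 (paralog / leading ambiguity / gap region /
fragment); these are not published quantities, so they were fixed once at
levels that give every filter a realistic workload. Taxon recovery is
drawn independently per locus, which understates the correlation real
loci show across taxa; the generator also makes no attempt at real
substitution-process realism (no rate variation along the sequence beyond
the conservation profile, no indel evolution model, no expression-level
effects). Passing the pipeline tests therefore demonstrates correct
mechanics and filter operating points, not biological fidelity of any
recovered signal.

A global pipeline seed fans out to per-stage seeds via
`(seed * 101 + stage) mod (2^31 - 1)` so stages can be re-run in
isolation; the same seed reproduces a run byte-for-byte.

# Problem sizes used in validation

The shipped test suite and acceptance checks use: 200 random alignments
of up to 60 columns for the block-selection oracle; 500 random 8-tip
binary-character instances plus 120 mixed 2-3-state instances for the
parsimony oracle; 8 random 3-5-tip trees for the likelihood enumeration
oracle (log tolerance 1e-10); 1,000 simulated null datasets of 100 sites
for KH calibration; one 5,000-site simulated alignment for branch
recovery; and pipeline runs of 8-40 loci for accounting, determinism and
filter-sensitivity checks. These sizes were chosen to exercise every code
path at desk scale.

# Known limitations

Alignment itself (MAFFT), assembly, HMM-based ortholog search, Bayesian
tree inference and divergence dating are out of scope; candidate
topologies enter as fixed trees. The masking step is an intent-level
approximation, not a reproduction, of the original masking tool. The
engine fits a single concatenated model rather than per-partition models.
Published figure-level p-values depend on the original 61,641-column
matrix and are not reproduction targets.
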