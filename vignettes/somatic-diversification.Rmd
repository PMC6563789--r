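---
title: "Methods: somatic diversification analysis for mosaic gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic diversification analysis for mosaic gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicdiv)
```

## The biological model

A mosaic immune gene family consists of genes whose diversified exon is a
concatenation, in fixed genomic order, of conserved sequence blocks
("elements").  Each gene carries a subset of the element library; the
presence/absence vector is its *element pattern*.  Within one animal, sperm
cells share an identical germline repertoire, while individual immune cells
(coelomocytes) carry somatically altered repertoires: whole genes deleted or
duplicated, and point substitutions accumulated — essentially never breaking
the reading frame.  The package's job is to measure those differences from
single-cell amplicon sequences and qPCR, and to test whether sequence
evolution tracks element patterns (pattern-pure phylogenetic clades).

Assumptions the pipeline inherits from this model:

* elements occur at most once per gene and in library order;
* the diversified exon is amplified by one degenerate primer pair sitting in
  conserved flanking sequence, so amplicon length differences reflect
  element content;
* somatic events act on whole genes (deletion, duplication) or single sites
  (substitution) — no partial-gene recombination;
* sequences compared for diversity statistics share a pattern and ungapped
  length, so per-column statistics need no length normalisation.

## Element decomposition and classification

`decompose_sequence()` aligns every library element consensus to the query
semi-globally (whole consensus against its best query window) under fixed
scoring — match +1, mismatch −1, gap open −4, gap extend −1 — chosen once so
results are bit-reproducible.  (The pairwise engine is
`Biostrings::pairwiseAlignment`; in its convention a gap of length $L$ costs
$4 + L$.)  An element is called *present* when

* identity = matches / consensus length ≥ `min_identity` (default **0.70**), and
* coverage = consensus bases aligned to query bases / consensus length ≥
  `min_coverage` (default **0.80**).

The defaults separate the two regimes the model cares about: simulated 5%
per-site divergence leaves identities near 0.9 and never drops an element,
while a fully deleted element leaves the consensus nothing to align to at
70% identity.  Because elements are ordered blocks, eligible calls must form
a chain of non-overlapping intervals in library order; the chain maximising
summed identity is selected by dynamic programming, ties resolved leftmost.
A query with more than half its bases unassigned is flagged
`LOW_CONFIDENCE` rather than rejected.  Classification
(`classify_pattern()`) is exact presence-vector matching against the
catalog; anything else is `NOVEL` — never a nearest-neighbour guess, so a
single dropped element cannot silently re-type a gene.

## Element-anchored multiple alignment

`element_align()` replaces a general-purpose progressive aligner with a
deterministic procedure that exploits the mosaic structure: each present
segment is aligned pairwise (Needleman–Wunsch, same scoring) to its element
consensus, and segments are stacked in consensus coordinates, pooling
insertions per consensus slot.  Absent elements become all-gap blocks — the
alignment's gaps literally mark missing elements.  Unassigned bases travel
in inter-element blocks (right-padded, unaligned); leading and trailing
unassigned bases (the primer flanks) go to the outermost blocks so that
flanks stack in shared columns even for patterns with few common elements.
The invariant checked on every run: ungapping any row reproduces its input
sequence exactly.

This aligner is deliberately not a general MSA tool: it requires a
decomposable input and never realigns across element boundaries.  Its
purpose is a reproducible column space for entropy, SNP and distance
statistics.

## Diversity statistics

Per column, over non-gap symbols with frequencies $f_s$:
$H = -\sum_s f_s \ln f_s$ (nats; $0\ln 0 = 0$).  Alignment-level diversity
is the arithmetic mean of column entropies, all-gap columns skipped and gaps
excluded from denominators; within the same-length, same-pattern groups the
statistic is defined for, gaps are rare and this choice is low-impact.  The
amino-acid profile translates each row in the common frame and repeats the
computation; the reported **ratio is amino-acid over nucleotide diversity**,
so values above 1 indicate an excess of non-synonymous variation.  (The
corresponding published table labels this column "nt/aa", but its printed
values equal aa ÷ nt; we compute what the values are.)

SNPs are polymorphic columns (≥ 2 distinct non-gap symbols among covering
rows); the *variation frequency* is `1 − max allele frequency`, and the
filtered set keeps columns strictly above the threshold (default 0.25).  We
count polymorphic columns, not column × allele variants — the plausible
alternative reading — and the per-column allele table is returned so either
count can be formed.

`check_orf()` translates the amplicon in a declared frame and reports
`FULL_ORF` iff no stop codon occurs before the final complete codon; a
terminal stop is tolerated and excluded from the amino-acid length.

## Repertoire comparison and ΔΔCT

`in_silico_pcr()` matches IUPAC-degenerate primers (forward, and the reverse
primer's reverse complement downstream of it) with at most `max_mismatch`
(default 2) mismatches, best hit per primer, ties 5′-most.  Fragment lengths
are merged into gel-style bands by single linkage at `resolution` bp
(default **30**, a deliberately coarse emulation of agarose-gel size
discrimination; every band-level claim is parameterised on it).
`missing_band_report()` flags germline bands with no focal band within the
resolution — the band-loss signature of somatic deletion — and focal-only
bands as novel.

`ddct_copy_ratio()` implements relative quantification:
$\Delta CT_x = Cq_{t,x} - Cq_{ref,x}$,
$\Delta\Delta CT = \Delta CT_{focal} - \Delta CT_{reference}$,
ratio $= E^{-\Delta\Delta CT}$ with amplification efficiency $E = 2$ fixed
(no efficiency correction is modelled; the parameter is exposed for
sensitivity analysis).  A target undetected in the focal sample is `ABSENT`
and rendered `"X"`; an undetected reference gene is an integrity error since
normalisation is impossible.

## Phylogenetics

Jukes–Cantor distance $d = -\tfrac34\ln(1 - \tfrac43 p)$, with $p$ the
mismatch fraction over pairwise-shared non-gap columns.  Pairwise deletion
(not complete deletion) is used because mosaic gaps would otherwise remove
most columns; this is a documented departure from generic practice.
$p \ge 0.75$ has no finite distance: `jc_distance()` raises a saturation
error, while `jc_distance_matrix(saturation = "cap")` caps $p$ at 0.7499 —
the mode used during bootstrap resampling, where transient saturation (or a
resampled pair with no shared columns) must not abort a replicate.

`nj_tree()` is canonical Saitou–Nei agglomeration on the Q criterion, ties
broken by lexicographic taxon-pair order so runs are deterministic; negative
branch lengths are clamped to zero with a warning.  The neighbor-joining
implementation is validated in the test suite against exhaustive topology
enumeration on ≤ 6 taxa (every additive matrix must return its generating
topology and path lengths) and against an independent NJ implementation.
Bootstrap support resamples alignment columns with replacement and scores
each original bipartition by the percentage of replicate trees containing
it; rendered Newick conventionally blanks supports ≤ 50 while the data keep
all values.  `clade_purity()` tests each pattern (or a declared group of
interchangeable patterns, e.g. `{01, 02}`) for monophyly by bipartition
membership on the unrooted tree and reports the violating leaves of the
smallest covering split.  We report per-pattern monophyly rather than a
clade count, because clade delimitation on an unrooted tree is not
well-defined.

## The synthetic-data generator

The simulator is first-class, tested code; its defaults are the study
conditions:

| parameter | default | rationale |
|---|---|---|
| `n_genotypes` | 3 | three animals sampled |
| `genes_per_genotype` | 7 | six-to-seven amplicon bands per animal |
| `n_elements` / `n_patterns` | 10 / 12 | 12 observed pattern categories |
| `element_len_range` | 90–150 nt (multiples of 3) | amplicon ORFs on the published 676–1,312 bp scale |
| `germline_divergence` | 0.05 subs/site | genotypes share no exact sequence |
| `p_del` / `p_dup` | 0.20 / 0.10 per gene | several of ~17–19 repertoire members missing per immune cell |
| `mu` | 0.002 subs/site | a few SNPs per somatic gene |
| `clones_per_cell` | 50 | ~86% clone redundancy at 7 genes |
| `cq_base`, `cq_noise_sd` | 21, 0.15 cycles | realistic single-copy Cq and replicate noise |

Pattern subsets always include the first and last library elements: in the
real family the terminal element is present in every gene (it is the element
whose sequence defines the gene name), and universally shared core elements
are what make cross-pattern alignment and distance computation meaningful.
Middle elements are included independently with probability 0.65.  Element
consensus sequences and primer flanks are drawn stop-free in frame; with
`orf_preserving = TRUE` element lengths must be multiples of 3 so that
whole-element absence never shifts frame, and somatic substitutions that
would create an in-frame stop are rejection-sampled (the simplest mechanism
consistent with the observed absence of pseudogenes, without asserting the
unknown biological one).  Primer flanks are excluded from substitution —
degenerate primers are designed against conserved sites, and mutating them
would conflate primer dropout with gene deletion.

Randomness uses a single user seed split hierarchically by
(genotype, cell, gene) through a deterministic string hash, so enlarging a
study never perturbs the cells already simulated, and equal seeds give
byte-identical FASTA/CSV outputs.

What the generator does *not* emulate: whole-genome-amplification bias
(`p_amp_fail` exists as a dropout toggle, default 0, but no MDA chemistry is
modelled), partial-gene recombination or element-level somatic shuffling,
immune-challenge dynamics, and sequencing error.  Passing tests therefore
demonstrate correctness of the statistics and the recoverability of the
simulated processes — not that real single-cell data are free of
amplification artefacts.

## Numerical choices and degenerate inputs

* Alignment scoring fixed (above); all tie-breaks deterministic (leftmost
  placement, first-maximum chain, lexicographic NJ pairs).
* Entropy frequencies must sum to 1 within 1e−9; distance-matrix symmetry is
  required to 1e−12.
* `0 · ln 0 ≡ 0`; all-gap columns are skipped; a zero nucleotide diversity
  makes the aa/nt ratio `NA` rather than infinite.
* Saturated or zero-overlap pairs: error in strict mode, capped in
  bootstrap/mosaic mode (above).
* Empty libraries, non-positive thresholds, mixed-pattern diversity groups,
  duplicate Cq rows and absent reference genes are contract errors with
  named offenders.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` run: 200 diverged genes for
pattern recovery; 500 somatic genes for ORF screening; 102 coelomocytes
(34 per genotype — the closest per-genotype multiple to a 100-cell study)
for deletion-rate recovery; exhaustive additive-matrix reconstruction over
all 123 unrooted topologies on 4–6 taxa; 20 independent seeds for clade
purity; 100 bootstrap replicates on a ~23-leaf tree.  These sizes give
binomial standard errors comfortably inside the tolerances they are checked
against (e.g. ±0.015 on the deletion-rate estimate at 714 gene trials).

## Known limitations

* The packaged element library is synthetic; real analyses must supply a
  library built from curated reference alignments, and decomposition quality
  then depends on that library's consensus fidelity.
* The aligner anchors on elements and will not recover homology that
  crosses element boundaries or involves novel (uncatalogued) elements.
* Jukes–Cantor is the only substitution model offered (matching the
  published analysis); no rate heterogeneity, no maximum likelihood or
  parsimony search.
* `estimate_deletion_rate()` assumes germline genes carry distinct patterns
  (guaranteed by the simulator, not by nature); with shared patterns it
  returns a lower bound.
* ΔΔCT assumes the fixed efficiency for all targets and a single-copy
  reference gene.
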