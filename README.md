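# mosaicdiv

Somatic diversification analysis for mosaic immune gene families.

Some invertebrate immune effector gene families — the sea urchin *SpTrf*
(*Sp185/333*) family is the motivating case — are "mosaic": every family
member's second exon is a concatenation, in fixed genomic order, of conserved
sequence blocks called **elements**, each of which is either present or
absent.  The presence/absence vector is the gene's **element pattern** (named
*A3*, *E2*, *01*, ...).  Comparing the gene repertoire of single germ cells
(sperm, identical within an animal) with single immune cells (coelomocytes)
reveals somatic diversification: whole-gene deletions and duplications plus
point substitutions that nonetheless keep every gene in frame.

`mosaicdiv` implements the complete analysis pipeline for such data, plus a
forward simulator that generates germline families and somatically
diversified single-cell genomes with full ground truth, so every stage can be
validated without external data:

* **Element-pattern typing** — semi-global placement of each library
  element's consensus on a query under fixed scoring, ordered non-overlapping
  calls selected by dynamic programming, exact-match classification against a
  pattern catalog (`decompose_sequence`, `classify_pattern`,
  `variant_group`).
* **Element-anchored multiple alignment** — per-element Needleman–Wunsch to
  the consensus, stacked in consensus coordinates; absent elements become
  all-gap blocks, and ungapping any row reproduces its input exactly
  (`element_align`).
* **Diversity statistics** — per-column Shannon entropy
  `H = -Σ f·ln f` over non-gap symbols, alignment means for nucleotide and
  amino-acid sequences and their aa/nt ratio (values above 1 indicate excess
  non-synonymous change); SNP calling with a variation-frequency filter
  (`vf = 1 − max allele frequency`, kept when strictly above the threshold);
  ORF integrity screening (`alignment_diversity`, `call_snps`, `check_orf`).
* **Repertoire comparison** — in-silico PCR with degenerate IUPAC primers
  and gel-style band binning, shared/unique sequence partitions,
  missing-band reports, and ΔΔCT qPCR copy ratios
  `ratio = 2^-((Cq_t,f − Cq_ref,f) − (Cq_t,r − Cq_ref,r))` with absent genes
  rendered `"X"` (`in_silico_pcr`, `compare_repertoires`,
  `ddct_copy_ratio`, `missing_band_report`).
* **Phylogenetics** — Jukes–Cantor distances
  `d = −(3/4)·ln(1 − 4p/3)` with pairwise gap deletion, deterministic
  Saitou–Nei neighbor joining, column-bootstrap support, and a clade-purity
  statistic testing whether each element pattern is monophyletic
  (`jc_distance`, `nj_tree`, `bootstrap_support`, `clade_purity`).
* **Simulation** — `sim_config`, `simulate_germline`, `simulate_cell`,
  `simulate_clones`, `simulate_cq`, `simulate_study`, and
  `estimate_deletion_rate`, which runs the typing → repertoire-comparison
  pipeline on simulated cells to recover the somatic deletion rate.

## Worked example

```r
library(mosaicdiv)

cfg   <- sim_config()                    # 3 animals, 7 genes each, defaults
study <- simulate_study(cfg, seed = 42)

study$germline
#> Simulated germline: 3 genotypes x 7 genes, 10 elements, 12 patterns

cell <- study$cells[["C1.1"]]            # one coelomocyte of animal 1
cell
#> Cell C1.1 (coelomocyte, genotype 1): 6 genes, 4 events

decompose_sequence(cell$genes$sequence[1], study$germline$library)
#> Decomposition: pattern B8
#>   elements present: e01 e02 e03 e04 e06 e09 e10
#>   unassigned fraction: 0.046

ddct_copy_table(study$cq, "C1.1", "S1.1")   # vs the animal's sperm
#>   target     ratio display
#> 1 g1_G01 0.9953476  0.9953
#> 2 g1_G02 0.9987693  0.9988
#> 3 g1_G03 1.0613221   1.061
#> 4 g1_G04 0.7450964  0.7451
#> 5 g1_G05 0.8616149  0.8616
#> 6 g1_G06        NA       X
#> 7 g1_G07 1.0483961   1.048

variant_group(study$clones[["C1.1"]]$sequence)$redundancy
#> [1] 0.88
```

Reading the output: this coelomocyte kept 6 of the animal's 7 germline genes
(4 logged somatic events); its first gene types to catalog pattern *B8* with
~5% of the amplicon outside element calls (the primer flanks).  The ΔΔCT
table normalises each target against the reference gene in both samples and
then against the sperm sample: ratios near 1 are diploid-equivalent, the `X`
row is the somatically deleted gene, and ratios near 2 would indicate a
duplication.  The clone library re-sequences the same few genes repeatedly,
giving 88% redundancy.

Real data enter through `read_fasta()` (amplicon FASTA),
`read_alignment_fasta()` (a curated alignment), `parse_seq_name()` (names
like `"S1-A3-2"`: source cell class, animal, element pattern, variant),
`read_element_library()` (a user-built element library JSON) and
`read_cq_table()` (Cq CSV with `"X"` for undetected targets).  The packaged
`default_element_library()` is a synthetic catalog for examples and
simulations; real analyses should supply a library built from reference
alignments.

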