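Package: mosaicdiv
Title: Somatic Diversification Analysis for Mosaic Immune Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for somatic diversification of mosaic immune
    gene families such as the sea urchin SpTrf (Sp185/333) family, whose
    second exon is built from conserved sequence blocks ("elements") that are
    present or absent in defined patterns.  Provides element-pattern
    decomposition and classification of amplicon sequences, a deterministic
    element-anchored multiple aligner, per-column Shannon entropy diversity
    and SNP statistics with variation-frequency filtering, ORF integrity
    screening, in-silico degenerate-primer PCR and gel-band profiling,
    germline-versus-somatic repertoire comparison, delta-delta-Ct qPCR copy
    ratios with absent-gene calls, Jukes-Cantor distances with
    neighbor-joining trees, bootstrap support and clade-purity testing, and a
    forward simulator of germline repertoires with somatic gene deletion,
    duplication and ORF-preserving point mutation that supplies ground truth
    for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
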