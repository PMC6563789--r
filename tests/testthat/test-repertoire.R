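test_that("in-silico PCR finds primer sites, skips broken genes, bins bands", {
  fwd <- "ACGTACGTAC"
  rev_site <- "GGTTCCAAGG"  # on the plus strand; rev primer is its RC
  rev <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev_site)))
  mid <- strrep("TCA", 40)
  gene <- paste0(fwd, mid, rev_site)
  no_rev <- paste0(fwd, mid)
  prof <- in_silico_pcr(data.frame(id = c("g1", "g2"),
                                   sequence = c(gene, no_rev)), fwd, rev)
  expect_equal(nrow(prof$fragments), 1L)
  expect_equal(prof$fragments$length, nchar(gene))

  # degenerate IUPAC primer with mismatches within tolerance
  fwd_deg <- "ACGTRCGTAC"
  gene_mm <- paste0("ACGTACTTAC", mid, rev_site)  # 1 mismatch to fwd
  prof2 <- in_silico_pcr(data.frame(id = "g", sequence = gene_mm),
                         fwd_deg, rev, max_mismatch = 2)
  expect_equal(nrow(prof2$fragments), 1L)
  expect_equal(nrow(in_silico_pcr(data.frame(id = "g", sequence = gene_mm),
                                  fwd_deg, rev, max_mismatch = 0)$fragments), 0L)

  # band binning: 700 and 710 merge at resolution 30; 1000 stays apart
  expect_equal(mosaicdiv:::.bin_bands(c(700, 710, 1000), 30)$band, c(705, 1000))
  expect_equal(mosaicdiv:::.bin_bands(c(700, 710, 1000), 30)$n, c(2L, 1L))
})

test_that("simulated germline amplifies at truth spans and pooled profiles contain cell bands", {
  cfg <- sim_config()
  germ <- simulate_germline(cfg, seed = 2)
  for (g in 1:2) {
    genes <- germ$genotypes[[g]]
    prof <- in_silico_pcr(data.frame(id = genes$gene_id, sequence = genes$sequence),
                          germ$primers$fwd, germ$primers$rev)
    expect_equal(sort(prof$fragments$length), sort(nchar(genes$sequence)))
    expect_lte(nrow(prof$bands), cfg$genes_per_genotype)
    # pooled multi-cell profile contains every band of each single cell
    cells <- lapply(1:3, function(k) {
      simulate_cell(germ, g, "coelomocyte", sprintf("C%d.%d", g, k))
    })
    pooled <- do.call(rbind, lapply(cells, function(cell) {
      data.frame(id = cell$genes$gene_id, sequence = cell$genes$sequence)
    }))
    pooled_prof <- in_silico_pcr(pooled, germ$primers$fwd, germ$primers$rev)
    for (cell in cells) {
      cp <- in_silico_pcr(data.frame(id = cell$genes$gene_id,
                                     sequence = cell$genes$sequence),
                          germ$primers$fwd, germ$primers$rev)
      for (b in cp$bands$band) {
        expect_true(any(abs(pooled_prof$bands$band - b) <= 30))
      }
    }
  }
})

test_that("repertoire comparison partitions by exact sequence and reports pattern loss", {
  a <- list(animal = 1, cell_class = "sperm",
            members = data.frame(sequence = c("AAA", "CCC", "GGG"),
                                 pattern = c("E2", "01", "D1")))
  expect_equal(length(compare_repertoires(a, a)$shared), 3L)
  expect_equal(length(compare_repertoires(a, a)$unique_a), 0L)

  b <- list(animal = 1, cell_class = "coelomocyte",
            members = data.frame(sequence = c("TTT", "CCA"),
                                 pattern = c("B3", "01")))
  cmp <- compare_repertoires(a, b)
  expect_equal(length(cmp$shared), 0L)
  expect_setequal(cmp$unique_a, c("AAA", "CCC", "GGG"))
  expect_setequal(cmp$patterns_only_in_a, c("E2", "D1"))
  # partition sizes and symmetry under swap
  expect_equal(length(cmp$shared) + length(cmp$unique_a), 3L)
  swp <- compare_repertoires(b, a)
  expect_equal(swp$unique_a, cmp$unique_b)
  expect_equal(swp$patterns_only_in_b, cmp$patterns_only_in_a)

  b$animal <- 2
  expect_error(compare_repertoires(a, b), "different animals")
  expect_silent(compare_repertoires(a, b, cross_animal = TRUE))
})

test_that("simulated deletion and mutation show up as pattern- and variant-level uniques", {
  cfg <- sim_config(p_dup = 0, mu = 0)
  germ <- simulate_germline(cfg, seed = 12)
  lib <- germ$library
  cell <- simulate_cell(germ, 1, "coelomocyte", "C1.1")
  deleted <- cell$events$gene_id[cell$events$event == "DELETE"]
  sperm <- germ$genotypes[[1]]
  cmp <- compare_repertoires(
    list(animal = 1, members = data.frame(sequence = sperm$sequence,
                                          pattern = sperm$pattern)),
    list(animal = 1, members = data.frame(sequence = cell$genes$sequence,
                                          pattern = cell$genes$pattern)))
  expect_setequal(cmp$patterns_only_in_a,
                  sperm$pattern[sperm$gene_id %in% deleted])
  expect_equal(length(cmp$unique_a), length(deleted))
})

test_that("delta-delta-Ct ratios follow the formula and render absence as X", {
  cq <- toy_cq()
  # all four Cq equal -> ratio 1
  r1 <- ddct_copy_ratio(cq, "t1", "sp", "sp")
  expect_equal(r1$ratio, 1)
  # ddCT = 1 -> ratio 0.5
  r2 <- ddct_copy_ratio(cq, "t1", "co", "sp")
  expect_equal(r2$ddct, 1)
  expect_equal(r2$ratio, 0.5)
  # reference gene against itself is exactly 1
  expect_equal(ddct_copy_ratio(cq, "SpGAPDH", "co", "sp")$ratio, 1)
  # absent target in focal -> ABSENT, rendered X
  r3 <- ddct_copy_ratio(cq, "t2", "co", "sp")
  expect_true(r3$absent)
  tab <- ddct_copy_table(cq, "co", "sp")
  expect_equal(tab$display[tab$target == "t2"], "X")
  # efficiency parameter
  expect_equal(ddct_copy_ratio(cq, "t1", "co", "sp", efficiency = 4)$ratio, 0.25)
  # absent reference cannot normalise
  cq_bad <- cq
  cq_bad$cq[cq_bad$sample_id == "co" & cq_bad$target == "SpGAPDH"] <- NA
  expect_error(ddct_copy_ratio(cq_bad, "t1", "co", "sp"), "cannot normalise")
})

test_that("noiseless Cq simulation inverts to exact copy ratios", {
  copies <- data.frame(
    sample_id = rep(c("sperm1", "cell1"), each = 3),
    cell_class = rep(c("sperm", "coelomocyte"), each = 3),
    target = rep(c("g1", "g2", "g3"), 2),
    copy = c(1, 1, 1, 2, 1, 0))
  cq <- simulate_cq(copies, noise_sd = 0, seed = 4)
  expect_equal(ddct_copy_ratio(cq, "g1", "cell1", "sperm1")$ratio, 2)
  expect_equal(ddct_copy_ratio(cq, "g2", "cell1", "sperm1")$ratio, 1)
  expect_true(ddct_copy_ratio(cq, "g3", "cell1", "sperm1")$absent)
  # copy doubling lowers Cq by exactly one cycle under zero noise
  expect_equal(cq$cq[cq$sample_id == "sperm1" & cq$target == "g1"] -
                 cq$cq[cq$sample_id == "cell1" & cq$target == "g1"], 1)
})

test_that("missing-band reports flag germline bands absent from the focal profile", {
  mk <- function(lengths) {
    structure(list(fragments = data.frame(id = seq_along(lengths),
                                          length = lengths),
                   bands = mosaicdiv:::.bin_bands(lengths, 30),
                   resolution = 30L), class = "amplicon_profile")
  }
  expect_equal(missing_band_report(mk(c(700, 800, 1000)), mk(c(700, 800, 1000))),
               list(missing = numeric(0), novel = numeric(0)))
  rep1 <- missing_band_report(mk(c(700, 800)), mk(c(700, 800, 1000)))
  expect_equal(rep1$missing, 1000)
  expect_equal(rep1$novel, numeric(0))
  # simulated deletion: band missing iff no other gene shares its bin
  cfg <- sim_config(p_dup = 0, mu = 0)
  germ <- simulate_germline(cfg, seed = 2)
  genes <- germ$genotypes[[1]]
  gl_prof <- in_silico_pcr(data.frame(id = genes$gene_id, sequence = genes$sequence),
                           germ$primers$fwd, germ$primers$rev)
  drop <- genes$gene_id[which.max(nchar(genes$sequence))]
  focal <- genes[genes$gene_id != drop, ]
  f_prof <- in_silico_pcr(data.frame(id = focal$gene_id, sequence = focal$sequence),
                          germ$primers$fwd, germ$primers$rev)
  rep2 <- missing_band_report(f_prof, gl_prof)
  dropped_len <- nchar(genes$sequence[genes$gene_id == drop])
  shares_bin <- any(abs(nchar(focal$sequence) - dropped_len) <= 30)
  expect_equal(length(rep2$missing) > 0, !shares_bin)
})
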