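test_that("Jukes-Cantor distance matches closed forms and the direct formula", {
  expect_equal(jc_distance("ACGTACGT", "ACGTACGT"), 0)
  # p = 0.25 over 8 shared columns (2 mismatches)... use 4 columns, 1 mismatch
  expect_equal(jc_distance("ACGT", "ACGA"), -0.75 * log(1 - 4 * 0.25 / 3))
  expect_equal(jc_distance("ACGT", "ACGA"), 0.3040988, tolerance = 1e-6)
  # pairwise deletion of gap columns
  expect_equal(jc_distance("AC-T", "ACG-"), 0)
  expect_error(jc_distance("AAAA", "CCCC"), "saturated")
  expect_error(jc_distance("----", "AAAA"), "shared")

  set.seed(41)
  for (i in 1:25) {
    n <- 60
    a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    b <- a
    swap <- sample(n, sample(0:20, 1))
    for (s in swap) b[s] <- sample(setdiff(c("A", "C", "G", "T"), a[s]), 1)
    p <- mean(a != b)
    d <- jc_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    expect_equal(d, -0.75 * log(1 - 4 * p / 3))
    expect_equal(d, jc_distance(paste(b, collapse = ""), paste(a, collapse = "")))
  }
})

test_that("JC distance matrix agrees with ape's implementation", {
  set.seed(52)
  rows <- vapply(1:6, function(i) {
    paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  }, "")
  base <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  rows <- vapply(1:6, function(i) substitute_at(base, sample(90, 8)), "")
  aln <- mosaic_alignment(paste0("t", 1:6), rows)
  D <- jc_distance_matrix(aln)
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(rows), "")))
  rownames(bin) <- paste0("t", 1:6)
  D_ape <- as.matrix(ape::dist.dna(bin, model = "JC69"))
  expect_equal(D, D_ape[rownames(D), colnames(D)], tolerance = 1e-10)
})

test_that("NJ solves the three-taxon tree exactly", {
  D <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  dd <- ape::cophenetic.phylo(tr)
  expect_equal(dd[rownames(D), colnames(D)], D)
  # three-point formulas: v_a = (d_ab + d_ac - d_bc)/2 = 1
  va <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "a")]
  expect_equal(va, 1)
})

test_that("NJ recovers every additive tree on 4-6 taxa (exhaustive topologies)", {
  set.seed(63)
  for (n in 4:6) {
    taxa <- letters[1:n]
    tops <- enumerate_topologies(taxa)
    expect_equal(length(tops), c(`4` = 3, `5` = 15, `6` = 105)[[as.character(n)]])
    for (tp in tops[sample(length(tops), min(12, length(tops)))]) {
      phy <- topology_to_phylo(tp)
      D <- additive_matrix(phy)
      rec <- nj_tree(D)
      expect_setequal(mosaicdiv:::.tree_splits(rec), mosaicdiv:::.tree_splits(phy))
      expect_equal(ape::cophenetic.phylo(rec)[rownames(D), colnames(D)], D,
                   tolerance = 1e-8)
    }
  }
})

test_that("NJ matches ape's neighbor joining on random matrices (independent oracle)", {
  set.seed(74)
  for (i in 1:5) {
    n <- 8
    phy <- ape::rtree(n, rooted = FALSE)
    D <- additive_matrix(phy)
    D <- D + matrix(runif(n * n, 0, 0.01), n, n)  # mild noise
    D <- (D + t(D)) / 2
    diag(D) <- 0
    mine <- nj_tree(D)
    theirs <- ape::nj(D)
    expect_setequal(mosaicdiv:::.tree_splits(mine), mosaicdiv:::.tree_splits(theirs))
  }
})

test_that("NJ contracts: asymmetry rejected, too-few taxa rejected, negatives clamped", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), ">= 3 taxa")
  D3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "not symmetric")
  # strongly non-additive matrix forces a negative branch -> clamped, warned
  D4 <- matrix(c(0, 0.57, 0.78, 1.82,
                 0.57, 0, 1.17, 0.44,
                 0.78, 1.17, 0, 1.80,
                 1.82, 0.44, 1.80, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- nj_tree(D4), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap supports clean clades at 100 and is seed-deterministic", {
  blockA <- strrep("A", 30)
  blockC <- strrep("C", 30)
  blockG <- strrep("G", 30)
  mk <- function(b1, b2, jitter) {
    substitute_at(paste0(b1, b2), jitter)
  }
  rows <- c(mk(blockA, blockC, 1), mk(blockA, blockC, 2), mk(blockA, blockC, 3),
            mk(blockG, blockA, 1), mk(blockG, blockA, 2), mk(blockG, blockA, 3))
  aln <- mosaic_alignment(paste0("t", 1:6), rows)
  tr <- bootstrap_support(aln, replicates = 50, seed = 9)
  splits <- attr(tr, "splits")
  clade1 <- paste(sort(c("t4", "t5", "t6")), collapse = "|")
  # the two-clade bipartition is t4|t5|t6 (side without t1)
  expect_true(clade1 %in% splits$split)
  expect_equal(splits$support[splits$split == clade1], 100)
  # determinism under the same seed
  tr2 <- bootstrap_support(aln, replicates = 50, seed = 9)
  expect_equal(attr(tr2, "splits"), splits)
  # one replicate: supports are 0 or 100 only
  tr3 <- bootstrap_support(aln, replicates = 1, seed = 3)
  expect_true(all(attr(tr3, "splits")$support %in% c(0, 100)))
  # supports are invariant under row permutation
  perm <- c(3, 1, 6, 2, 4, 5)
  aln_p <- mosaic_alignment(paste0("t", 1:6)[perm], rows[perm])
  tr4 <- bootstrap_support(aln_p, replicates = 50, seed = 9)
  s4 <- attr(tr4, "splits")
  expect_setequal(s4$split, splits$split)
  # newick rendering suppresses low supports but the data keeps them
  f <- tempfile(fileext = ".nwk")
  write_tree_newick(tr, f, suppress_at = 100)
  expect_false(grepl("100", readLines(f)))
})

test_that("clade purity detects monophyly and identifies violators", {
  # every pattern a cherry
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1,(c1:1,c2:1):1);")
  lab <- setNames(c("A", "A", "B", "B", "C", "C"),
                  c("a1", "a2", "b1", "b2", "c1", "c2"))
  cp <- clade_purity(tr, lab)
  expect_equal(cp$purity, 1)

  # graft one A leaf inside the B clade
  tr2 <- ape::read.tree(text = "((a1:1,a2:1):1,((b1:1,a3:1):1,b2:1):1,(c1:1,c2:1):1);")
  lab2 <- c(lab, a3 = "A")
  cp2 <- clade_purity(tr2, lab2)
  expect_lt(cp2$purity, 1)
  bad <- cp2$report[!cp2$report$monophyletic, ]
  expect_true("A" %in% bad$pattern)
  # brute-force oracle: check A monophyly by enumerating all splits
  splits <- mosaicdiv:::.tree_splits(tr2)
  sides <- strsplit(splits, "|", fixed = TRUE)
  S <- names(lab2)[lab2 == "A"]
  tips <- tr2$tip.label
  mono_oracle <- any(vapply(c(sides, lapply(sides, function(s) setdiff(tips, s))),
                            function(side) setequal(side, S), TRUE))
  expect_false(mono_oracle)
  # the foreign leaf inside A's smallest covering clade is flagged
  expect_true(grepl("b1", bad$violators[bad$pattern == "A"]))

  # single-pattern tree: vacuously pure
  cp3 <- clade_purity(tr, setNames(rep("Z", 6), names(lab)))
  expect_equal(cp3$purity, 1)

  # declared pattern groups merge before testing
  lab4 <- setNames(c("01", "02", "B", "B", "C", "C"), names(lab))
  cp4 <- clade_purity(tr, lab4, groups = list(c("01", "02")))
  expect_equal(cp4$purity, 1)
  expect_true("01/02" %in% cp4$report$pattern)

  expect_error(clade_purity(tr, lab[-1]), "unlabeled")
})

test_that("trees on simulated pattern clades reflect input distances", {
  # germline genes carry independent 5% divergence, so different genes
  # (patterns) form separated clades; within-clade variants add ~1%
  germ <- simulate_germline(sim_config(), seed = 31)
  lib <- germ$library
  set.seed(311)
  base <- germ$genotypes[[1]]$sequence[1:4]
  seqs <- unlist(lapply(base, function(s) {
    vapply(1:5, function(i) substitute_at(s, sample(nchar(s), round(0.01 * nchar(s)))), "")
  }))
  rec <- data.frame(id = sprintf("q%02d", seq_along(seqs)), sequence = seqs)
  aln <- element_align(rec, lib)
  D <- jc_distance_matrix(aln, saturation = "cap")
  tr <- nj_tree(D)
  Dt <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  r <- cor(D[upper.tri(D)], Dt[upper.tri(Dt)])
  expect_gt(r, 0.95)
})
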