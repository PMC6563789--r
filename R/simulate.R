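# Forward simulator: germline mosaic gene families and somatically
# diversified single-cell genomes with full ground truth.  Sperm cells carry
# the unmodified germline repertoire (identical within a genotype);
# coelomocytes acquire whole-gene deletions, duplications and point
# substitutions that, by default, are rejected when they would create an
# in-frame stop codon (the family shows an almost complete lack of
# pseudogenes).  One RNG stream per simulation, split hierarchically by
# (genotype, cell, gene), so adding cells never perturbs earlier draws.

.PATTERN_NAMES <- c("A3", "C2", "D1", "C3", "D5", "B3", "E2", "01", "02",
                    "G1", "B8", "D2", "A6", "E3", "F1", "C5")


.nonstop_codons <- function() {
  all <- as.vector(outer(outer(.DNA, .DNA, paste0), .DNA, paste0))
  setdiff(all, .STOPS)
}

# random in-frame, stop-free sequence of length L (multiple of 3)
.random_orf_seq <- function(L) {
  stopifnot(L %% 3L == 0L)
  paste(sample(.nonstop_codons(), L / 3L, replace = TRUE), collapse = "")
}

# per-site substitution at `rate`; under orf_preserving, substitutions that
# would create an in-frame stop are resampled among the remaining bases (a
# site is skipped if every alternative creates a stop).  `protect` marks
# sites exempt from substitution (the conserved primer-binding flanks the
# degenerate primers are designed against).
.mutate_seq <- function(seq, rate, orf_preserving = TRUE, protect = integer(0)) {
  if (rate <= 0) return(list(sequence = seq, n_subs = 0L, sites = integer(0)))
  ch <- .chars(seq)
  hit <- setdiff(which(runif(length(ch)) < rate), protect)
  sites <- integer(0)
  for (i in hit) {
    alts <- setdiff(.DNA, ch[i])
    if (orf_preserving) {
      cod <- (i - 1L) %/% 3L
      pos <- (i - 1L) %% 3L + 1L
      codon <- ch[(cod * 3L + 1L):(cod * 3L + 3L)]
      ok <- vapply(alts, function(b) {
        codon[pos] <- b
        !(paste(codon, collapse = "") %in% .STOPS)
      }, TRUE)
      alts <- alts[ok]
    }
    if (!length(alts)) next
    ch[i] <- if (length(alts) == 1L) alts else sample(alts, 1L)
    sites <- c(sites, i)
  }
  list(sequence = paste(ch, collapse = ""), n_subs = length(sites), sites = sites)
}

#' Simulation configuration
#'
#' Defaults describe a sea-urchin-scale study: three animals (genotypes),
#' seven mosaic genes per diploid genotype drawn from a 12-pattern catalog
#' over 10 elements, second-exon amplicons in the several-hundred-bp range,
#' one sperm and one coelomocyte sampled per animal, ~50 sequenced clones
#' per cell, and modest somatic rates.
#'
#' @param n_genotypes Number of animals (genotypes).
#' @param n_elements Elements in the shared library.
#' @param n_patterns Named patterns in the catalog (must fit the subsets
#'   with both core elements fixed, `2^(n_elements - 2)`).
#' @param genes_per_genotype Germline family size per genotype.
#' @param element_len_range Consensus length range in nt; lengths are drawn
#'   in multiples of 3 so whole-element differences keep reading frames.
#' @param flank_len Length of the primer-binding flanks (multiple of 3).
#' @param germline_divergence Substitutions/site separating each genotype
#'   from the shared ancestral gene set (0 makes all genotypes identical).
#' @param p_del Per-gene somatic deletion probability (coelomocytes).
#' @param p_dup Per-gene somatic duplication probability (surviving genes;
#'   copy number 2 after an event).
#' @param mu Somatic per-site substitution rate (subs/site).
#' @param orf_preserving Reject substitutions creating in-frame stops.
#' @param n_sperm,n_coelomocytes Cells simulated per class per genotype.
#' @param clones_per_cell Clones sampled (with replacement, proportional to
#'   copy number) per cell.
#' @param cq_base Baseline Cq (cycles) for a single-copy target.
#' @param cq_noise_sd Gaussian Cq noise (cycles).
#' @param p_amp_fail Optional per-gene amplification-failure probability
#'   (whole-genome-amplification dropout toggle; default off).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genotypes = 3L, n_elements = 10L, n_patterns = 12L,
                       genes_per_genotype = 7L,
                       element_len_range = c(90L, 150L), flank_len = 21L,
                       germline_divergence = 0.05,
                       p_del = 0.2, p_dup = 0.1, mu = 0.002,
                       orf_preserving = TRUE,
                       n_sperm = 1L, n_coelomocytes = 1L,
                       clones_per_cell = 50L,
                       cq_base = 21, cq_noise_sd = 0.15, p_amp_fail = 0) {
  cfg <- list(n_genotypes = as.integer(n_genotypes),
              n_elements = as.integer(n_elements),
              n_patterns = as.integer(n_patterns),
              genes_per_genotype = as.integer(genes_per_genotype),
              element_len_range = as.integer(element_len_range),
              flank_len = as.integer(flank_len),
              germline_divergence = germline_divergence,
              p_del = p_del, p_dup = p_dup, mu = mu,
              orf_preserving = isTRUE(orf_preserving),
              n_sperm = as.integer(n_sperm),
              n_coelomocytes = as.integer(n_coelomocytes),
              clones_per_cell = as.integer(clones_per_cell),
              cq_base = cq_base, cq_noise_sd = cq_noise_sd,
              p_amp_fail = p_amp_fail)
  probs <- c(cfg$p_del, cfg$p_dup, cfg$p_amp_fail, cfg$germline_divergence)
  if (any(probs < 0 | probs > 1)) .stopf("probabilities must be in [0, 1]")
  if (cfg$mu < 0) .stopf("mu must be >= 0")
  if (cfg$n_patterns > 2^(max(cfg$n_elements - 2L, 0L))) {
    .stopf("n_patterns (%d) exceeds the %d subsets of %d elements with both core elements fixed",
           cfg$n_patterns, 2^(max(cfg$n_elements - 2L, 0L)), cfg$n_elements)
  }
  if (cfg$n_patterns < cfg$genes_per_genotype) {
    .stopf("need at least as many catalog patterns as genes per genotype")
  }
  if (cfg$orf_preserving &&
      (any(cfg$element_len_range %% 3L != 0L) || cfg$flank_len %% 3L != 0L)) {
    .stopf("element and flank lengths must be multiples of 3 when orf_preserving")
  }
  if (cfg$n_patterns > length(.PATTERN_NAMES)) {
    .stopf("at most %d named patterns supported", length(.PATTERN_NAMES))
  }
  structure(cfg, class = "sim_config")
}

# degenerate version of a primer-binding site: every 3rd position is widened
# to a two-fold IUPAC code containing the true base
.degenerate_primer <- function(site) {
  ch <- .chars(site)
  wide <- c(A = "R", G = "R", C = "Y", T = "Y")
  idx <- seq(3L, length(ch), by = 3L)
  ch[idx] <- wide[ch[idx]]
  paste(ch, collapse = "")
}

#' Simulate a germline mosaic gene family
#'
#' Draws a shared element library (stop-free, in-frame consensus sequences),
#' a catalog of distinct named element patterns, and an ancestral gene set of
#' `genes_per_genotype` genes with distinct patterns.  Each genotype's
#' germline is the ancestral set diverged by `germline_divergence`
#' substitutions/site, so exact cross-genotype sequence sharing has
#' probability ~0 at the default divergence.  Every gene carries shared
#' primer-binding flanks around its element core; the returned degenerate
#' primers amplify the full second-exon region of every gene.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sim_germline`: `library` (an
#'   [element_library()] with the full catalog), `primers` (`fwd`, `rev`,
#'   IUPAC strings), `genotypes` (list of data frames `gene_id`, `pattern`,
#'   `sequence`), `ancestral` (data frame), `cfg`, `seed`.
#' @export
simulate_germline <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  lib <- .with_seed(.sub_seed(seed, "library"), {
    lens <- sample(seq(cfg$element_len_range[1], cfg$element_len_range[2], by = 3L),
                   cfg$n_elements, replace = TRUE)
    elements <- data.frame(index = seq_len(cfg$n_elements),
                           name = sprintf("e%02d", seq_len(cfg$n_elements)),
                           consensus = vapply(lens, .random_orf_seq, ""),
                           stringsAsFactors = FALSE)
    # distinct presence subsets; the first and last elements are core --
    # present in every family member (the terminal element is the one that
    # defines the gene name) -- and the middle elements vary at inclusion
    # probability 0.65, giving mosaic patterns that always share sequence
    pats <- list()
    while (length(pats) < cfg$n_patterns) {
      v <- runif(cfg$n_elements) < 0.65
      v[c(1L, cfg$n_elements)] <- TRUE
      if (any(vapply(pats, identical, TRUE, y = v))) next
      pats[[length(pats) + 1L]] <- v
    }
    names(pats) <- .PATTERN_NAMES[seq_len(cfg$n_patterns)]
    element_library(elements, pats)
  })
  flanks <- .with_seed(.sub_seed(seed, "flanks"), {
    list(f = .random_orf_seq(cfg$flank_len), r = .random_orf_seq(cfg$flank_len))
  })
  primers <- list(
    fwd = .degenerate_primer(flanks$f),
    rev = .degenerate_primer(as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(flanks$r))))
  )
  gene_seq <- function(pattern_name) {
    pres <- lib$patterns[pattern_name, ]
    paste0(flanks$f, paste(lib$elements$consensus[pres], collapse = ""), flanks$r)
  }
  ancestral <- .with_seed(.sub_seed(seed, "ancestral"), {
    pats <- sample(rownames(lib$patterns), cfg$genes_per_genotype)
    data.frame(gene_id = sprintf("G%02d", seq_len(cfg$genes_per_genotype)),
               pattern = pats,
               sequence = vapply(pats, gene_seq, ""),
               stringsAsFactors = FALSE)
  })
  flank_sites <- function(n) c(seq_len(cfg$flank_len),
                               seq(n - cfg$flank_len + 1L, n))
  genotypes <- lapply(seq_len(cfg$n_genotypes), function(g) {
    df <- ancestral
    df$sequence <- vapply(seq_len(nrow(df)), function(i) {
      .with_seed(.sub_seed(seed, "germline", g, df$gene_id[i]), {
        .mutate_seq(df$sequence[i], cfg$germline_divergence,
                    cfg$orf_preserving,
                    protect = flank_sites(nchar(df$sequence[i])))$sequence
      })
    }, "")
    rownames(df) <- NULL
    df
  })
  structure(list(library = lib, primers = primers, flanks = flanks,
                 genotypes = genotypes, ancestral = ancestral,
                 cfg = cfg, seed = as.integer(seed)),
            class = "sim_germline")
}

#' @export
print.sim_germline <- function(x, ...) {
  cat(sprintf("Simulated germline: %d genotypes x %d genes, %d elements, %d patterns\n",
              x$cfg$n_genotypes, x$cfg$genes_per_genotype,
              nrow(x$library$elements), nrow(x$library$patterns)))
  invisible(x)
}

#' Simulate a single-cell genome from a germline
#'
#' Sperm cells return the germline repertoire unchanged (somatic rates are
#' forced to 0), so all sperm of a genotype are identical.  For a
#' coelomocyte, each gene is deleted with probability `p_del`; each surviving
#' gene is duplicated with probability `p_dup` (copy number 2) and mutated at
#' `mu` substitutions/site, with stop-creating substitutions rejected when
#' `orf_preserving`.  All events are logged.
#'
#' @param germ A [simulate_germline()] result.
#' @param genotype Genotype index (1-based).
#' @param class `"sperm"` or `"coelomocyte"`.
#' @param cell_id Cell identifier string (part of the RNG split).
#' @param seed Integer seed; defaults to the germline's seed.
#' @return List of class `cell_genome`: `cell_id`, `class`, `genotype`,
#'   `genes` (data frame `gene_id`, `pattern`, `sequence`, `copy`), `events`
#'   (data frame `event`, `gene_id`, `detail`).
#' @export
simulate_cell <- function(germ, genotype, class = c("coelomocyte", "sperm"),
                          cell_id = "c1", seed = germ$seed) {
  stopifnot(inherits(germ, "sim_germline"))
  class <- match.arg(class)
  cfg <- germ$cfg
  genes <- germ$genotypes[[genotype]]
  events <- list()
  if (class == "sperm") {
    genes$copy <- 1L
  } else {
    keep <- logical(nrow(genes))
    copy <- integer(nrow(genes))
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]
      .with_seed(.sub_seed(seed, "cell", genotype, cell_id, gid), {
        if (runif(1) < cfg$p_del) {
          events[[length(events) + 1L]] <- data.frame(
            event = "DELETE", gene_id = gid, detail = "", stringsAsFactors = FALSE)
        } else {
          keep[i] <- TRUE
          copy[i] <- 1L
          if (runif(1) < cfg$p_dup) {
            copy[i] <- 2L
            events[[length(events) + 1L]] <- data.frame(
              event = "DUPLICATE", gene_id = gid, detail = "copy=2",
              stringsAsFactors = FALSE)
          }
          n_i <- nchar(genes$sequence[i])
          mut <- .mutate_seq(genes$sequence[i], cfg$mu, cfg$orf_preserving,
                             protect = c(seq_len(cfg$flank_len),
                                         seq(n_i - cfg$flank_len + 1L, n_i)))
          if (mut$n_subs > 0L) {
            genes$sequence[i] <- mut$sequence
            events[[length(events) + 1L]] <- data.frame(
              event = "SUBSTITUTE", gene_id = gid,
              detail = paste(mut$sites, collapse = ","), stringsAsFactors = FALSE)
          }
        }
      })
    }
    genes <- genes[keep, , drop = FALSE]
    genes$copy <- copy[keep]
    rownames(genes) <- NULL
  }
  ev <- if (length(events)) do.call(rbind, events) else {
    data.frame(event = character(0), gene_id = character(0), detail = character(0))
  }
  structure(list(cell_id = cell_id, class = class, genotype = genotype,
                 genes = genes, events = ev),
            class = "cell_genome")
}

#' @export
print.cell_genome <- function(x, ...) {
  cat(sprintf("Cell %s (%s, genotype %d): %d genes, %d events\n",
              x$cell_id, x$class, x$genotype, nrow(x$genes), nrow(x$events)))
  invisible(x)
}

#' Sample a clone library from a cell genome
#'
#' Clones are drawn with replacement, each draw proportional to gene copy
#' number, emulating cloning and Sanger sequencing of the cell's amplicons.
#'
#' @param cell A [simulate_cell()] result with at least one gene.
#' @param clones_per_cell Number of clones.
#' @param seed Integer seed.
#' @return Data frame `clone_id`, `gene_id`, `pattern`, `sequence`.
#' @export
simulate_clones <- function(cell, clones_per_cell = 50L, seed = 1L) {
  stopifnot(inherits(cell, "cell_genome"), nrow(cell$genes) >= 1L)
  idx <- .with_seed(.sub_seed(seed, "clones", cell$genotype, cell$cell_id), {
    sample.int(nrow(cell$genes), clones_per_cell, replace = TRUE,
               prob = cell$genes$copy)
  })
  data.frame(clone_id = sprintf("%s_clone%03d", cell$cell_id, seq_len(clones_per_cell)),
             gene_id = cell$genes$gene_id[idx],
             pattern = cell$genes$pattern[idx],
             sequence = cell$genes$sequence[idx],
             stringsAsFactors = FALSE)
}

#' Simulate a qPCR Cq table from true copy numbers
#'
#' The forward model for the delta-delta-Ct analysis:
#' `Cq = base - log2(copy) + Normal(0, noise_sd)`, with copy 0 rendered
#' absent (`NA`, written `"X"`), and the reference gene fixed at copy 1 per
#' haploid equivalent in every sample.
#'
#' @param copies Data frame with columns `sample_id`, `cell_class`, `target`,
#'   `copy` (non-negative).
#' @param noise_sd Gaussian Cq noise in cycles.
#' @param seed Integer seed.
#' @param base Baseline Cq for a single-copy target.
#' @param reference_target Reference gene name added at copy 1 per sample.
#' @return A `cq_table` (see [read_cq_table()]).
#' @export
simulate_cq <- function(copies, noise_sd = 0.15, seed = 1L, base = 21,
                        reference_target = "SpGAPDH") {
  stopifnot(is.data.frame(copies),
            all(c("sample_id", "cell_class", "target", "copy") %in% names(copies)))
  if (any(copies$copy < 0)) .stopf("copy numbers must be >= 0")
  samples <- unique(copies[c("sample_id", "cell_class")])
  ref <- data.frame(sample_id = samples$sample_id, cell_class = samples$cell_class,
                    target = reference_target, copy = 1, stringsAsFactors = FALSE)
  all <- rbind(copies, ref)
  cqv <- .with_seed(.sub_seed(seed, "cq"), {
    ifelse(all$copy == 0, NA_real_,
           base - log2(pmax(all$copy, 1e-12)) + rnorm(nrow(all), 0, noise_sd))
  })
  validate_cq_table(
    data.frame(sample_id = all$sample_id, cell_class = all$cell_class,
               target = all$target, cq = cqv, stringsAsFactors = FALSE),
    reference_target)
}

#' Simulate a complete single-cell study with ground truth
#'
#' Wraps [simulate_germline()], [simulate_cell()], [simulate_clones()] and
#' [simulate_cq()] into one study: per genotype, `n_sperm` sperm and
#' `n_coelomocytes` coelomocytes, a clone library per cell, and a Cq table
#' over all cells with the sperm sample of each genotype as germline
#' reference.  The `truth` component records the germline repertoire, every
#' cell's event log and the true copy-number table — sufficient to recompute
#' every downstream expectation without re-simulation.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return List of class `sim_study`: `germline`, `cells` (list of
#'   `cell_genome`), `clones` (list of data frames, by cell id), `cq`
#'   (a `cq_table`), `truth` (list: `copies` data frame, `events` by cell,
#'   `germline_patterns` by genotype).
#' @export
simulate_study <- function(cfg = sim_config(), seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  germ <- simulate_germline(cfg, seed)
  cells <- list()
  for (g in seq_len(cfg$n_genotypes)) {
    for (k in seq_len(cfg$n_sperm)) {
      id <- sprintf("S%d.%d", g, k)
      cells[[id]] <- simulate_cell(germ, g, "sperm", id, seed)
    }
    for (k in seq_len(cfg$n_coelomocytes)) {
      id <- sprintf("C%d.%d", g, k)
      cells[[id]] <- simulate_cell(germ, g, "coelomocyte", id, seed)
    }
  }
  clones <- lapply(cells, simulate_clones,
                   clones_per_cell = cfg$clones_per_cell, seed = seed)
  copies <- do.call(rbind, lapply(names(cells), function(id) {
    cell <- cells[[id]]
    germ_genes <- germ$genotypes[[cell$genotype]]$gene_id
    cp <- setNames(integer(length(germ_genes)), germ_genes)
    cp[cell$genes$gene_id] <- cell$genes$copy
    data.frame(sample_id = id, cell_class = cell$class,
               target = sprintf("g%d_%s", cell$genotype, germ_genes),
               copy = as.integer(cp), stringsAsFactors = FALSE)
  }))
  cq <- simulate_cq(copies, noise_sd = cfg$cq_noise_sd, seed = seed,
                    base = cfg$cq_base)
  truth <- list(
    copies = copies,
    events = lapply(cells, `[[`, "events"),
    germline_patterns = lapply(germ$genotypes, `[[`, "pattern")
  )
  structure(list(germline = germ, cells = cells, clones = clones,
                 cq = cq, truth = truth, cfg = cfg, seed = as.integer(seed)),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("Simulated study: %d genotypes, %d cells, %d clones/cell\n",
              x$cfg$n_genotypes, length(x$cells), x$cfg$clones_per_cell))
  invisible(x)
}

#' Estimate the somatic deletion rate from simulated cells
#'
#' Runs the analysis pipeline on a simulated study: each cell's gene
#' sequences are decomposed against the study's element library and
#' classified to patterns, each coelomocyte's pattern repertoire is compared
#' to its genotype's germline (sperm) repertoire with
#' [compare_repertoires()], and the deletion rate is estimated as the
#' fraction of germline genes whose pattern is missing from the cell, pooled
#' over cells.  Germline genes carry distinct patterns, so a missing pattern
#' is a deleted gene.
#'
#' @param study A [simulate_study()] result.
#' @return List with `estimate`, `n_missing`, `n_genes` (pooled counts).
#' @export
estimate_deletion_rate <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  germ <- study$germline
  lib <- germ$library
  germline_patterns <- lapply(seq_len(germ$cfg$n_genotypes), function(g) {
    vapply(germ$genotypes[[g]]$sequence,
           function(s) decompose_sequence(s, lib)$pattern, "")
  })
  n_missing <- 0L
  n_genes <- 0L
  for (cell in study$cells) {
    if (cell$class != "coelomocyte") next
    cell_patterns <- vapply(cell$genes$sequence,
                            function(s) decompose_sequence(s, lib)$pattern, "")
    cmp <- compare_repertoires(
      list(animal = cell$genotype, cell_class = "sperm",
           members = data.frame(sequence = germ$genotypes[[cell$genotype]]$sequence,
                                pattern = germline_patterns[[cell$genotype]],
                                stringsAsFactors = FALSE)),
      list(animal = cell$genotype, cell_class = "coelomocyte",
           members = data.frame(sequence = cell$genes$sequence,
                                pattern = cell_patterns,
                                stringsAsFactors = FALSE)))
    n_missing <- n_missing + length(cmp$patterns_only_in_a)
    n_genes <- n_genes + length(germline_patterns[[cell$genotype]])
  }
  list(estimate = n_missing / n_genes, n_missing = n_missing, n_genes = n_genes)
}
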