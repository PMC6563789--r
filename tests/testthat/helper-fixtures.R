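# Shared fixtures, built in code.

# tiny two-element library with one catalog pattern per subset
toy_library <- function() {
  element_library(
    data.frame(index = 1:3,
               name = c("e1", "e2", "e3"),
               consensus = c("ACGTACGTACGT", "GGTTCCAAGGTTCCAA", "TTGACCATTGAC"),
               stringsAsFactors = FALSE),
    patterns = list(P12 = c("e1", "e2"),
                    P13 = c("e1", "e3"),
                    P123 = c("e1", "e2", "e3"),
                    P2 = "e2"))
}

toy_concat <- function(lib, pattern) {
  pres <- lib$patterns[pattern, ]
  paste(lib$elements$consensus[pres], collapse = "")
}

write_toy_fasta <- function(lines, path = tempfile(fileext = ".fasta")) {
  writeLines(lines, path)
  path
}

# substitute k positions of a sequence deterministically spread out
substitute_at <- function(seq, positions, to = "A") {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  }
  paste(ch, collapse = "")
}

# small Cq table fixture
toy_cq <- function() {
  validate_cq_table(data.frame(
    sample_id = rep(c("sp", "co"), each = 3),
    cell_class = rep(c("sperm", "coelomocyte"), each = 3),
    target = rep(c("SpGAPDH", "t1", "t2"), 2),
    cq = c(20, 20, 20, 20, 21, NA),
    stringsAsFactors = FALSE))
}

# additive distance matrix from an ape tree
additive_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[sort(rownames(d)), sort(rownames(d))]
}

# Enumerate all unrooted binary topologies on the given taxa by recursive
# leaf insertion into every edge (3, 15, 105, ... trees for 4, 5, 6 taxa).
# Trees are nested lists; the top level is the central trichotomy.
# Independent oracle for the NJ tests.
enumerate_topologies <- function(taxa) {
  stopifnot(length(taxa) >= 3)
  grow <- function(tree, leaf) {
    out <- list()
    rec <- function(node, replace) {
      out[[length(out) + 1L]] <<- replace(list(node, leaf))
      if (is.list(node)) {
        for (i in seq_along(node)) {
          local({
            ii <- i
            nn <- node
            rec(nn[[ii]], function(x) {
              nn[[ii]] <- x
              replace(nn)
            })
          })
        }
      }
    }
    for (i in seq_along(tree)) {
      local({
        ii <- i
        rec(tree[[ii]], function(x) {
          t2 <- tree
          t2[[ii]] <- x
          t2
        })
      })
    }
    out
  }
  trees <- list(list(taxa[1], taxa[2], taxa[3]))
  for (k in seq_along(taxa)[-(1:3)]) {
    trees <- unlist(lapply(trees, grow, leaf = taxa[k]), recursive = FALSE)
  }
  trees
}

# nested-list topology -> ape phylo with random positive branch lengths
topology_to_phylo <- function(tree) {
  to_newick <- function(node) {
    if (!is.list(node)) return(node)
    paste0("(", paste(vapply(node, to_newick, ""), collapse = ","), ")")
  }
  phy <- ape::read.tree(text = paste0(to_newick(tree), ";"))
  phy$edge.length <- round(runif(nrow(phy$edge), 0.05, 1), 3)
  phy
}
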