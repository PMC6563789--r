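# Jukes-Cantor distances, neighbor-joining, bootstrap support, and the
# clade-vs-element-pattern purity statistic.

#' Jukes-Cantor distance between two gapped alignment rows
#'
#' Gap columns are removed pairwise (a column counts only when both rows
#' carry a base); `p` is the mismatch fraction over shared columns and the
#' distance is `-(3/4) ln(1 - 4p/3)` substitutions/site.  `p >= 0.75` has no
#' finite Jukes-Cantor distance and raises a saturation error.
#'
#' @param row_a,row_b Gapped rows of equal length.
#' @return Distance in substitutions/site.
#' @examples
#' jc_distance("ACGT", "ACGT")  # 0
#' @export
jc_distance <- function(row_a, row_b) {
  if (nchar(row_a) != nchar(row_b)) .stopf("rows differ in length")
  a <- .chars(row_a); b <- .chars(row_b)
  shared <- a != "-" & b != "-"
  if (!any(shared)) .stopf("no shared non-gap column")
  p <- mean(a[shared] != b[shared])
  if (p >= 0.75) .stopf("saturated pair (p = %.3f >= 0.75): no finite Jukes-Cantor distance", p)
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix of an alignment
#'
#' @param aln A [mosaic_alignment()].
#' @param saturation `"error"` raises on saturated pairs (`p >= 0.75`);
#'   `"cap"` caps `p` just below 0.75 (used during bootstrap resampling,
#'   where resampled columns can transiently saturate a pair).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
jc_distance_matrix <- function(aln, saturation = c("error", "cap")) {
  stopifnot(inherits(aln, "mosaic_alignment"))
  saturation <- match.arg(saturation)
  M <- .aln_matrix(aln)
  n <- nrow(M)
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- M[i, ] != "-" & M[j, ] != "-"
      if (!any(shared)) {
        if (saturation == "error") {
          .stopf("rows %s and %s share no non-gap column", aln$ids[i], aln$ids[j])
        }
        p <- 0.7499  # no shared column: treat like a saturated pair
      } else {
        p <- mean(M[i, shared] != M[j, shared])
      }
      if (p >= 0.75) {
        if (saturation == "error") {
          .stopf("saturated pair (%s, %s): p = %.3f", aln$ids[i], aln$ids[j], p)
        }
        p <- 0.7499
      }
      D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical Saitou-Nei agglomeration with the Q criterion.  Ties in Q are
#' broken by lexicographic order of the joined taxon-pair labels, making the
#' result deterministic.  Negative branch lengths are clamped to 0 with a
#' warning.
#'
#' @param D Symmetric distance matrix with taxon dimnames (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) .stopf("D must be a square matrix")
  if (max(abs(D - t(D))) > 1e-12) .stopf("distance matrix is not symmetric")
  n <- nrow(D)
  if (n < 3L) .stopf("neighbor joining needs >= 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # each active node holds a newick fragment; joins build subtrees
  frag <- labels
  key <- labels  # lexicographic tie-break key: smallest leaf label in subtree
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  while (length(frag) > 3L) {
    m <- length(frag)
    r <- rowSums(D)
    # Q matrix; pick min, ties by lexicographic (key_i, key_j) sorted
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        pair <- sort(c(key[i], key[j]))
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pair[1] < best$pair[1] ||
              (pair[1] == best$pair[1] && pair[2] < best$pair[2])))) {
          best <- list(q = q, i = i, j = j, pair = pair)
        }
      }
    }
    i <- best$i; j <- best$j
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    vi <- bl(vi); vj <- bl(vj)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
    newkey <- min(key[i], key[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    key <- c(key[keep], newkey)
    D <- D2
  }
  va <- bl((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  vb <- bl((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  vc <- bl((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped) warning("negative branch length(s) clamped to 0")
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1], va, frag[2], vb, frag[3], vc)
  ape::read.tree(text = nwk)
}

# Non-trivial bipartitions of an unrooted tree, canonicalised as the side
# NOT containing the alphabetically first taxon, keyed as a sorted,
# "|"-joined string.
.tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  out <- character(0)
  for (cl in pp) {
    side <- tree$tip.label[cl]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    if (length(side) >= 2L && length(side) <= length(tips) - 2L) {
      out <- c(out, paste(sort(side), collapse = "|"))
    }
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Builds the tree from the full alignment (Jukes-Cantor + neighbor
#' joining), then resamples alignment columns with replacement `replicates`
#' times, rebuilds the tree for each replicate, and scores each internal
#' bipartition of the original tree by the percentage of replicate trees
#' containing it.  All supports are retained in the returned data; rendered
#' output conventionally suppresses supports of 50 or below
#' (see `suppress_at` in [write_tree_newick()]).
#'
#' @param aln A [mosaic_alignment()] with >= 4 rows.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed for column resampling.
#' @return The original `ape::phylo` tree with an added `splits` attribute:
#'   data frame of bipartition keys and `support` percentages, also written
#'   to `tree$node.label` where a split maps to an internal node.
#' @export
bootstrap_support <- function(aln, replicates = 100L, seed = 1L) {
  stopifnot(inherits(aln, "mosaic_alignment"), replicates >= 1L)
  M <- .aln_matrix(aln)
  # zero-distance ties routinely clamp a branch during resampling; the
  # clamp warning is informative for direct nj_tree() calls, noise here
  base_tree <- suppressWarnings(nj_tree(jc_distance_matrix(aln, saturation = "cap")))
  base_splits <- .tree_splits(base_tree)
  counts <- setNames(numeric(length(base_splits)), base_splits)
  .with_seed(seed, {
    for (b in seq_len(replicates)) {
      cols <- sample.int(ncol(M), ncol(M), replace = TRUE)
      rep_aln <- mosaic_alignment(aln$ids, apply(M[, cols, drop = FALSE], 1, paste, collapse = ""))
      rep_tree <- suppressWarnings(nj_tree(jc_distance_matrix(rep_aln, saturation = "cap")))
      hit <- .tree_splits(rep_tree)
      found <- base_splits %in% hit
      counts[found] <- counts[found] + 1
    }
  })
  support <- 100 * counts / replicates
  splits <- data.frame(split = base_splits, support = as.numeric(support),
                       stringsAsFactors = FALSE)
  base_tree$node.label <- .splits_to_node_labels(base_tree, splits)
  attr(base_tree, "splits") <- splits
  base_tree
}

.splits_to_node_labels <- function(tree, splits) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  lab <- character(tree$Nnode)
  for (k in seq_along(pp)) {
    side <- tree$tip.label[pp[[k]]]
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    keyk <- paste(sort(side), collapse = "|")
    i <- match(keyk, splits$split)
    lab[k] <- if (!is.na(i)) sprintf("%g", splits$support[i]) else ""
  }
  lab
}

#' Write a tree to Newick, optionally suppressing low bootstrap supports
#'
#' @param tree An `ape::phylo`, typically from [bootstrap_support()].
#' @param path Output path.
#' @param suppress_at Node labels (supports) less than or equal to this value
#'   are blanked in the rendered Newick; the tree object keeps them all.
#'   Use `NULL` to keep every label.
#' @export
write_tree_newick <- function(tree, path, suppress_at = 50) {
  out <- tree
  if (!is.null(suppress_at) && !is.null(out$node.label)) {
    v <- suppressWarnings(as.numeric(out$node.label))
    out$node.label[!is.na(v) & v <= suppress_at] <- ""
  }
  ape::write.tree(out, file = path)
  invisible(path)
}

#' Clade purity of element patterns on a tree
#'
#' Tests, for each element pattern (or declared group of interchangeable
#' patterns), whether its leaves form one side of a bipartition of the
#' unrooted tree — i.e. are monophyletic.  Purity is the fraction of
#' patterns that are monophyletic.  For a non-monophyletic pattern the
#' violating leaves are the foreign leaves inside the smallest bipartition
#' side containing the pattern.
#'
#' @param tree An unrooted `ape::phylo`.
#' @param labels Named character vector: leaf id -> pattern name; every leaf
#'   must be labeled.
#' @param groups Optional list of character vectors declaring pattern groups
#'   treated as one clade label (e.g. `list(c("01", "02"))`).
#' @return List of class `clade_purity`: `purity`, and `report` — data frame
#'   with `pattern`, `n_leaves`, `monophyletic`, `violators`.
#' @export
clade_purity <- function(tree, labels, groups = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(labels))) {
    .stopf("unlabeled leaf/leaves: %s",
           paste(setdiff(tips, names(labels)), collapse = ", "))
  }
  lab <- labels[tips]
  if (!is.null(groups)) {
    for (g in groups) {
      lab[lab %in% g] <- paste(sort(g), collapse = "/")
    }
  }
  n <- length(tips)
  splits <- .tree_splits(tree)
  sides <- lapply(strsplit(splits, "|", fixed = TRUE), identity)
  # each split has two sides; collect both
  all_sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)))
  rows <- lapply(sort(unique(lab)), function(p) {
    S <- tips[lab == p]
    mono <- length(S) <= 1L || length(S) >= n - 1L ||
      any(vapply(all_sides, function(side) setequal(side, S), TRUE))
    viol <- character(0)
    if (!mono) {
      covers <- Filter(function(side) all(S %in% side), all_sides)
      covers <- c(covers, list(tips))
      sizes <- vapply(covers, length, 0L)
      minimal <- covers[[which.min(sizes)]]
      viol <- setdiff(minimal, S)
    }
    data.frame(pattern = p, n_leaves = length(S), monophyletic = mono,
               violators = paste(viol, collapse = ","), stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  structure(list(purity = mean(report$monophyletic), report = report),
            class = "clade_purity")
}

#' @export
print.clade_purity <- function(x, ...) {
  cat(sprintf("Clade purity: %.2f (%d/%d patterns monophyletic)\n",
              x$purity, sum(x$report$monophyletic), nrow(x$report)))
  bad <- x$report[!x$report$monophyletic, ]
  if (nrow(bad)) {
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  %s: violated by %s\n", bad$pattern[i], bad$violators[i]))
    }
  }
  invisible(x)
}
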