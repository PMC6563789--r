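# Element-pattern decomposition: place each library element's consensus on the
# query by semi-global alignment, then keep the best-scoring chain of calls
# that respects library order (elements occur as ordered genomic blocks).

# Fixed alignment scoring, chosen for bit-reproducibility:
# match +1, mismatch -1, gap open -4, gap extend -1 (Biostrings convention:
# a gap of length L costs open + L*extend).

.submat <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                baseOnly = FALSE)
  m
}

#' Decompose a sequence into library elements
#'
#' Each element consensus is aligned semi-globally to the query (whole
#' consensus against the best local window) under fixed scoring (match +1,
#' mismatch -1, gap open -4, gap extend -1).  An element is called present
#' when its identity (matches / consensus length) is at least `min_identity`
#' and at least `min_coverage` of its consensus aligns to query bases.
#' Because elements occur as ordered blocks, calls must form a chain of
#' non-overlapping intervals in library order; the chain maximising summed
#' identity is selected by dynamic programming (ties resolved leftmost).
#'
#' @param seq Nucleotide string (A/C/G/T).
#' @param lib An [element_library()].
#' @param min_identity Minimum identity fraction to call an element present.
#' @param min_coverage Minimum fraction of the consensus aligned to query
#'   bases.
#' @return An object of class `decomposition`: list with `presence` (named
#'   logical over elements), `pattern` (catalog name or `"NOVEL"`),
#'   `elements` (data frame of present calls: `name`, `start`, `end`
#'   1-based inclusive, `identity`), `unassigned_fraction` and
#'   `low_confidence` (TRUE when more than half of the query is unassigned).
#' @examples
#' lib <- element_library(data.frame(index = 1:2, name = c("e1", "e2"),
#'                                   consensus = c("ACGTACGTAC", "GGTTGGTTGG")),
#'                        patterns = list(P1 = c("e1", "e2")))
#' decompose_sequence("ACGTACGTACGGTTGGTTGG", lib)$pattern
#' @export
decompose_sequence <- function(seq, lib, min_identity = 0.70, min_coverage = 0.80) {
  stopifnot(inherits(lib, "element_library"))
  if (nrow(lib$elements) == 0L) .stopf("empty element library")
  if (!(min_identity > 0 && min_identity <= 1 && min_coverage > 0 && min_coverage <= 1)) {
    .stopf("identity/coverage thresholds must be in (0, 1]")
  }
  seq <- toupper(seq)
  .check_alphabet(seq, "<query>")
  if (nchar(seq) < min(nchar(lib$elements$consensus))) {
    .stopf("query (%d nt) shorter than the shortest element", nchar(seq))
  }

  cons <- Biostrings::DNAStringSet(lib$elements$consensus)
  names(cons) <- lib$elements$name
  aln <- Biostrings::pairwiseAlignment(
    pattern = cons, subject = Biostrings::DNAString(seq),
    type = "global-local", substitutionMatrix = .submat(),
    gapOpening = 4, gapExtension = 1
  )
  len <- nchar(lib$elements$consensus)
  nm <- Biostrings::nmatch(aln)
  # consensus bases aligned to query bases = consensus length minus the
  # consensus bases opposite subject gaps (the "insertion" widths)
  ni <- Biostrings::nindel(aln)
  aligned_bases <- len - Biostrings::insertion(ni)[, "WidthSum"]
  cand <- data.frame(
    name = lib$elements$name,
    start = Biostrings::start(Biostrings::subject(aln)),
    end = Biostrings::end(Biostrings::subject(aln)),
    identity = nm / len,
    coverage = aligned_bases / len,
    stringsAsFactors = FALSE
  )
  eligible <- cand$identity >= min_identity & cand$coverage >= min_coverage

  # max-weight chain over eligible candidates, library order, non-overlapping
  idx <- which(eligible)
  k <- length(idx)
  keep <- logical(nrow(cand))
  if (k > 0L) {
    best <- cand$identity[idx]
    prev <- integer(k)
    for (i in seq_len(k)) {
      prev[i] <- 0L
      bi <- cand$identity[idx[i]]
      if (i > 1L) for (j in seq_len(i - 1L)) {
        if (cand$end[idx[j]] < cand$start[idx[i]] && best[j] + cand$identity[idx[i]] > bi) {
          bi <- best[j] + cand$identity[idx[i]]
          prev[i] <- j
        }
      }
      best[i] <- bi
    }
    at <- which.max(best)  # which.max takes the first (leftmost) maximum
    while (at > 0L) {
      keep[idx[at]] <- TRUE
      at <- prev[at]
    }
  }

  presence <- setNames(keep, lib$elements$name)
  calls <- cand[keep, c("name", "start", "end", "identity")]
  rownames(calls) <- NULL
  covered <- if (nrow(calls)) sum(calls$end - calls$start + 1L) else 0L
  unassigned <- 1 - covered / nchar(seq)
  structure(list(
    presence = presence,
    pattern = classify_pattern(presence, lib),
    elements = calls,
    unassigned_fraction = unassigned,
    low_confidence = unassigned > 0.5
  ), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("Decomposition: pattern %s%s\n", x$pattern,
              if (x$low_confidence) " [LOW_CONFIDENCE]" else ""))
  cat(sprintf("  elements present: %s\n",
              paste(names(x$presence)[x$presence], collapse = " ")))
  cat(sprintf("  unassigned fraction: %.3f\n", x$unassigned_fraction))
  invisible(x)
}

#' Classify a presence vector against the pattern catalog
#'
#' Exact presence-vector matching only: a vector differing from every catalog
#' entry in any slot is `"NOVEL"` — never a nearest-neighbour guess.
#'
#' @param presence Logical vector over the library elements.
#' @param lib An [element_library()] (its `patterns` matrix is the catalog).
#' @return The catalog pattern name, or `"NOVEL"`.
#' @export
classify_pattern <- function(presence, lib) {
  stopifnot(inherits(lib, "element_library"))
  pm <- lib$patterns
  if (length(presence) != ncol(pm) && nrow(pm) > 0L) {
    .stopf("presence vector length %d != library size %d", length(presence), ncol(pm))
  }
  for (p in rownames(pm)) {
    if (all(pm[p, ] == presence)) return(p)
  }
  "NOVEL"
}

#' Assign variant numbers within one element pattern
#'
#' Sequences typed to the same element pattern are sub-categorised into
#' sequence variants: identical sequences share a variant number, numbered by
#' first occurrence.  Redundancy is the fraction of sequences that repeat an
#' already-seen variant, `1 - unique/total`.
#'
#' @param seqs Character vector of sequences (all typed to one pattern).
#' @return List with `variant` (integer vector parallel to `seqs`),
#'   `n_unique`, and `redundancy`.
#' @export
variant_group <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  variant <- match(seqs, unique(seqs))
  list(variant = variant, n_unique = length(unique(seqs)),
       redundancy = 1 - length(unique(seqs)) / length(seqs))
}
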