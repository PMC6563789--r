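# Deterministic element-anchored multiple alignment.  Each sequence is first
# decomposed into library elements; per element, present segments are aligned
# pairwise (Needleman-Wunsch) to the element consensus and stacked in
# consensus coordinates; absent elements become all-gap blocks, reproducing
# the mosaic structure where alignment gaps indicate missing elements.
# Unassigned bases (linkers/flanks) are carried in inter-element blocks so
# that ungapping any row reproduces its input sequence exactly.

#' Construct a mosaic alignment from gapped rows
#'
#' @param ids Character vector of row identifiers.
#' @param rows Character vector of gapped rows (gap `-`), all equal length.
#' @param column_class Optional integer vector of length `nchar(rows[1])`
#'   giving the library element index of each column (`NA` for inter-element
#'   columns).
#' @return An object of class `mosaic_alignment`.
#' @export
mosaic_alignment <- function(ids, rows, column_class = NULL) {
  stopifnot(length(ids) == length(rows), length(rows) >= 1L)
  L <- unique(nchar(rows))
  if (length(L) != 1L) .stopf("alignment rows must all have the same length")
  if (!is.null(column_class)) stopifnot(length(column_class) == L)
  structure(list(ids = as.character(ids), rows = as.character(rows),
                 ncol = L, column_class = column_class),
            class = "mosaic_alignment")
}

#' @export
print.mosaic_alignment <- function(x, ...) {
  cat(sprintf("Mosaic alignment: %d rows x %d columns\n", length(x$rows), x$ncol))
  invisible(x)
}

#' Remove gaps from alignment rows
#' @param aln A `mosaic_alignment`.
#' @return Character vector of ungapped sequences, named by row id.
#' @export
ungap_rows <- function(aln) {
  stopifnot(inherits(aln, "mosaic_alignment"))
  setNames(gsub("-", "", aln$rows, fixed = TRUE), aln$ids)
}

#' Element-anchored multiple alignment
#'
#' @param records Data frame of sequence records (see [read_fasta()]).
#' @param lib An [element_library()].
#' @param min_identity,min_coverage Decomposition thresholds passed to
#'   [decompose_sequence()].
#' @param force Align even when some decomposition is low-confidence
#'   (more than half of a query unassigned); refused otherwise.
#' @return A `mosaic_alignment` with `column_class` set (element index per
#'   element block, `NA` for inter-element columns) and an attached
#'   `decompositions` list.
#' @export
element_align <- function(records, lib, min_identity = 0.70,
                          min_coverage = 0.80, force = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L,
            inherits(lib, "element_library"))
  n <- nrow(records)
  dec <- lapply(records$sequence, decompose_sequence, lib = lib,
                min_identity = min_identity, min_coverage = min_coverage)
  low <- vapply(dec, `[[`, logical(1), "low_confidence")
  if (any(low) && !force) {
    .stopf("low-confidence decomposition for record(s) %s; use force = TRUE to align anyway",
           paste(records$id[low], collapse = ", "))
  }

  E <- nrow(lib$elements)
  # per sequence: element segments and linker slots 1..E+1 (slot i+1 = after
  # library element i).  Leading bases always go to the outermost slot 1 and
  # trailing bases to slot E+1, so shared flanks stack in common blocks even
  # when two patterns have no element in common.
  seg <- matrix(NA_character_, nrow = n, ncol = E)
  linker <- matrix("", nrow = n, ncol = E + 1L)
  for (s in seq_len(n)) {
    x <- toupper(records$sequence[s])
    calls <- dec[[s]]$elements
    pos <- 1L
    for (k in seq_len(nrow(calls))) {
      e <- match(calls$name[k], lib$elements$name)
      if (calls$start[k] > pos) {
        slot <- if (k == 1L) 1L else match(calls$name[k - 1L], lib$elements$name) + 1L
        linker[s, slot] <- substr(x, pos, calls$start[k] - 1L)
      }
      seg[s, e] <- substr(x, calls$start[k], calls$end[k])
      pos <- calls$end[k] + 1L
    }
    if (pos <= nchar(x)) {
      linker[s, E + 1L] <- substr(x, pos, nchar(x))
    }
  }

  rows <- rep("", n)
  classes <- integer(0)
  pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
  emit_linker <- function(slot) {
    w <- max(nchar(linker[, slot]))
    if (w > 0L) {
      rows <<- paste0(rows, vapply(linker[, slot], pad, "", w = w))
      classes <<- c(classes, rep(NA_integer_, w))
    }
  }
  emit_linker(1L)
  for (e in seq_len(E)) {
    present <- which(!is.na(seg[, e]))
    if (length(present)) {
      block <- .stack_on_consensus(seg[present, e], lib$elements$consensus[e])
      w <- nchar(block$rows[1])
      blockrows <- rep(strrep("-", w), n)
      blockrows[present] <- block$rows
      rows <- paste0(rows, blockrows)
      classes <- c(classes, rep(lib$elements$index[e], w))
    }
    emit_linker(e + 1L)
  }

  aln <- mosaic_alignment(records$id, rows, classes)
  attr(aln, "decompositions") <- dec
  aln
}

# Align each segment globally to the consensus, then merge in consensus
# coordinates: insertions relative to the consensus are pooled per consensus
# slot and right-padded to the deepest insertion seen there.
.stack_on_consensus <- function(segments, consensus) {
  L <- nchar(consensus)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(segments),
    subject = Biostrings::DNAString(consensus),
    type = "global", substitutionMatrix = .submat(),
    gapOpening = 4, gapExtension = 1
  )
  # pattern = segment, subject = consensus
  seg_al <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
  con_al <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
  m <- length(segments)
  res <- matrix("-", nrow = m, ncol = L)
  ins <- matrix("", nrow = m, ncol = L + 1L)
  for (i in seq_len(m)) {
    cpos <- 0L
    ci <- con_al[[i]]; si <- seg_al[[i]]
    for (k in seq_along(ci)) {
      if (ci[k] != "-") {
        cpos <- cpos + 1L
        res[i, cpos] <- si[k]
      } else {
        ins[i, cpos + 1L] <- paste0(ins[i, cpos + 1L], si[k])
      }
    }
  }
  width <- apply(nchar(ins), 2, max)
  out <- character(m)
  for (i in seq_len(m)) {
    parts <- character(0)
    for (p in seq_len(L + 1L)) {
      if (width[p] > 0L) {
        parts <- c(parts, paste0(ins[i, p], strrep("-", width[p] - nchar(ins[i, p]))))
      }
      if (p <= L) parts <- c(parts, res[i, p])
    }
    out[i] <- paste(parts, collapse = "")
  }
  list(rows = out)
}

#' Write a mosaic alignment as aligned FASTA
#' @param aln A `mosaic_alignment`.
#' @param path Output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "mosaic_alignment"))
  write_fasta(data.frame(id = aln$ids, sequence = aln$rows,
                         stringsAsFactors = FALSE), path)
}

#' Read an aligned FASTA into a mosaic alignment
#' @param path Aligned FASTA path (gap character `-`).
#' @param tolerant Accept IUPAC ambiguity codes.
#' @export
read_alignment_fasta <- function(path, tolerant = FALSE) {
  rec <- read_fasta(path, aligned = TRUE, tolerant = tolerant)
  mosaic_alignment(rec$id, rec$sequence)
}
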