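# Column-wise Shannon entropy diversity, SNP calling with the
# variation-frequency filter, and ORF integrity screening.

#' Non-gap symbol frequencies of an alignment column
#'
#' @param column Character vector of single symbols (one per row; `-` = gap).
#' @return List with `freq` (named numeric, fractions over non-gap symbols
#'   summing to 1) and `gap_fraction`.  `freq` is empty for an all-gap column.
#' @export
column_frequencies <- function(column) {
  stopifnot(is.character(column))
  gaps <- column == "-"
  obs <- column[!gaps]
  freq <- if (length(obs)) table(obs) / length(obs) else table(character(0))
  list(freq = setNames(as.numeric(freq), names(freq)),
       gap_fraction = mean(gaps))
}

#' Shannon entropy of a column frequency vector (nats)
#'
#' Computes `-sum(freq * ln(freq))` over non-gap symbols, with the usual
#' convention `0 * ln(0) = 0`.  A monomorphic column has entropy 0; a
#' balanced biallelic column `ln 2`; a uniform k-symbol column `ln k`.
#'
#' @param freq Named numeric vector of symbol frequencies summing to 1
#'   (or the list returned by [column_frequencies()]).
#' @return Entropy in nats.
#' @export
column_entropy <- function(freq) {
  if (is.list(freq)) freq <- freq$freq
  if (length(freq) == 0L) return(0)
  if (any(freq < 0)) .stopf("negative frequency")
  if (abs(sum(freq) - 1) > 1e-9) .stopf("frequencies must sum to 1 (got %.12f)", sum(freq))
  f <- freq[freq > 0]
  -sum(f * log(f))
}

.aln_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$rows, "", fixed = TRUE))
}

#' Alignment-wide entropy diversity profile
#'
#' Diversity is the per-column Shannon entropy `-sum(freq * ln(freq))`,
#' averaged over alignment columns (all-gap columns skipped; gaps excluded
#' from the frequency denominator).  The statistic is computed within groups
#' of sequences of the same ungapped length and element pattern.  When
#' `translate = TRUE` the rows are also translated in a common reading frame
#' and the amino-acid diversity computed the same way; the reported ratio is
#' amino-acid diversity over nucleotide diversity, so values above 1 indicate
#' an excess of non-synonymous change.
#'
#' @param aln A [mosaic_alignment()]; rows must share ungapped length.
#' @param translate Also compute amino-acid diversity and the aa/nt ratio.
#' @param frame Reading frame (0, 1 or 2) for translation.
#' @param pattern Optional character vector of per-row pattern names; if
#'   given, mixed patterns are a contract error (the statistic is defined
#'   within one pattern).
#' @return A list of class `diversity_profile`: `entropy_nt` (per column),
#'   `mean_nt`, and when `translate`, `entropy_aa`, `mean_aa` and `ratio`
#'   (`NA` when `mean_nt` is 0).
#' @export
alignment_diversity <- function(aln, translate = TRUE, frame = 0L, pattern = NULL) {
  stopifnot(inherits(aln, "mosaic_alignment"))
  if (!is.null(pattern) && length(unique(pattern)) > 1L) {
    .stopf("diversity is defined within one element pattern; got: %s",
           paste(unique(pattern), collapse = ", "))
  }
  ungapped <- ungap_rows(aln)
  if (length(unique(nchar(ungapped))) != 1L) {
    .stopf("diversity is defined for sequences of the same ungapped length")
  }
  M <- .aln_matrix(aln)
  ent <- apply(M, 2, function(col) column_entropy(column_frequencies(col)))
  keep <- colSums(M != "-") > 0
  out <- list(entropy_nt = ent, mean_nt = mean(ent[keep]))
  if (translate) {
    aa <- vapply(ungapped, .translate_frame, "", frame = frame)
    A <- do.call(rbind, strsplit(aa, "", fixed = TRUE))
    ent_aa <- apply(A, 2, function(col) column_entropy(column_frequencies(col)))
    out$entropy_aa <- ent_aa
    out$mean_aa <- mean(ent_aa)
    out$ratio <- if (out$mean_nt > 0) out$mean_aa / out$mean_nt else NA_real_
  }
  structure(out, class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat(sprintf("Diversity profile over %d nt columns\n", length(x$entropy_nt)))
  cat(sprintf("  mean nt diversity: %.4f nats\n", x$mean_nt))
  if (!is.null(x$mean_aa)) {
    cat(sprintf("  mean aa diversity: %.4f nats\n", x$mean_aa))
    cat(sprintf("  aa/nt ratio:       %s\n",
                if (is.na(x$ratio)) "NA" else sprintf("%.2f", x$ratio)))
  }
  invisible(x)
}

.translate_frame <- function(seq, frame = 0L) {
  s <- substr(seq, frame + 1L, nchar(seq))
  s <- substr(s, 1L, (nchar(s) %/% 3L) * 3L)
  if (!nzchar(s)) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(s)))
}

#' Call SNP columns and filter by variation frequency
#'
#' A column is a SNP when at least two distinct non-gap symbols occur among
#' the rows covering it.  Its variation frequency is the fraction of covering
#' rows that do not carry the majority symbol (`1 - max allele frequency`).
#' The filtered set keeps SNPs with variation frequency strictly above
#' `vf_threshold`.
#'
#' @param aln A [mosaic_alignment()] with at least 2 rows.
#' @param vf_threshold Variation-frequency cutoff (strict `>`).
#' @return List with `snps` (data frame: `column` 1-based, `n_alleles`,
#'   `alleles` comma-joined `symbol:count`, `variation_frequency`) and
#'   `filtered` (the subset with vf > threshold).
#' @export
call_snps <- function(aln, vf_threshold = 0.25) {
  stopifnot(inherits(aln, "mosaic_alignment"))
  if (length(aln$rows) < 2L) .stopf("SNP calling needs >= 2 rows")
  M <- .aln_matrix(aln)
  rows <- lapply(seq_len(ncol(M)), function(j) {
    col <- M[, j][M[, j] != "-"]
    tab <- table(col)
    if (length(tab) < 2L) return(NULL)
    data.frame(column = j, n_alleles = length(tab),
               alleles = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                               collapse = ","),
               variation_frequency = 1 - max(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  snps <- do.call(rbind, rows)
  if (is.null(snps)) {
    snps <- data.frame(column = integer(0), n_alleles = integer(0),
                       alleles = character(0), variation_frequency = numeric(0))
  }
  list(snps = snps,
       filtered = snps[snps$variation_frequency > vf_threshold, , drop = FALSE])
}

#' Screen an amplicon for ORF integrity
#'
#' Translates the amplicon in the given frame with the standard genetic code.
#' The ORF is intact (`FULL_ORF`) when no stop codon occurs before the final
#' complete codon; a stop as the final codon is tolerated as a terminator and
#' excluded from the amino-acid length.
#'
#' @param seq Nucleotide string, length >= 3.
#' @param frame Reading frame: 0, 1 or 2.
#' @return List of class `orf_report`: `frame`, `aa_length`,
#'   `has_internal_stop`, `status` (`"FULL_ORF"` or `"BROKEN"`).
#' @examples
#' check_orf("ATGAAACCC")$status   # FULL_ORF
#' check_orf("ATGTAACCC")$status   # BROKEN
#' @export
check_orf <- function(seq, frame = 0L) {
  seq <- toupper(seq)
  stopifnot(nchar(seq) >= 3L, frame %in% 0:2)
  s <- substr(seq, frame + 1L, nchar(seq))
  n_codons <- nchar(s) %/% 3L
  if (n_codons == 0L) {
    return(structure(list(frame = frame, aa_length = 0L,
                          has_internal_stop = FALSE, status = "FULL_ORF"),
                     class = "orf_report"))
  }
  codons <- substring(s, 3L * (seq_len(n_codons) - 1L) + 1L, 3L * seq_len(n_codons))
  is_stop <- codons %in% .STOPS
  internal <- any(is_stop[-n_codons])
  aa_length <- n_codons - as.integer(is_stop[n_codons])
  structure(list(frame = as.integer(frame), aa_length = aa_length,
                 has_internal_stop = internal,
                 status = if (internal) "BROKEN" else "FULL_ORF"),
            class = "orf_report")
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf("ORF (frame %d): %s, %d aa\n", x$frame, x$status, x$aa_length))
  invisible(x)
}
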