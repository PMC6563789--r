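# Repertoire comparison between cell classes: in-silico degenerate-primer
# PCR with gel-style band binning, shared/unique sequence sets, and
# delta-delta-Ct qPCR copy ratios with absent-gene calls.

# Count mismatches of an IUPAC primer at each offset; returns best hit as
# c(start, mismatches) or NULL.  Ties broken 5'-most.
.best_primer_site <- function(primer, seq, max_mismatch, from = 1L) {
  hits <- list()
  for (mm in 0:max_mismatch) {
    m <- Biostrings::matchPattern(primer, seq, max.mismatch = mm, fixed = FALSE)
    st <- Biostrings::start(m)
    st <- st[st >= from]
    if (length(st)) return(c(start = st[1], mismatch = mm))
  }
  NULL
}

#' In-silico PCR over a gene set with degenerate primers
#'
#' For each gene, finds the best (fewest-mismatch, then 5'-most) forward
#' primer site and the best reverse site (the reverse complement of the
#' reverse primer) downstream of it, under IUPAC-aware matching with at most
#' `max_mismatch` mismatches per primer.  The amplicon length is the
#' inclusive span from forward start to reverse-site end.  Genes lacking
#' either site contribute nothing.  Fragment lengths are then merged into
#' gel-style bands: lengths within `resolution` bp of a band member join
#' that band (single linkage), emulating the size discrimination of gel
#' electrophoresis.
#'
#' @param genes Data frame of sequence records (columns `id`, `sequence`).
#' @param fwd,rev Primer strings over the IUPAC alphabet (both given
#'   5'->3' as synthesised).
#' @param max_mismatch Maximum mismatches tolerated per primer site.
#' @param resolution Band-merging resolution in bp.
#' @return Object of class `amplicon_profile`: list with `fragments`
#'   (data frame `id`, `length`, `start`, `end`) and `bands` (data frame
#'   `band` representative length (rounded mean), `n` multiplicity),
#'   sorted ascending.
#' @export
in_silico_pcr <- function(genes, fwd, rev, max_mismatch = 2L, resolution = 30L) {
  stopifnot(is.data.frame(genes), all(c("id", "sequence") %in% names(genes)))
  fwd <- Biostrings::DNAString(toupper(fwd))
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(toupper(rev)))
  frag <- list()
  for (i in seq_len(nrow(genes))) {
    s <- Biostrings::DNAString(toupper(genes$sequence[i]))
    f <- .best_primer_site(fwd, s, max_mismatch)
    if (is.null(f)) next
    r <- .best_primer_site(rev_rc, s, max_mismatch, from = f[["start"]] + length(fwd))
    if (is.null(r)) next
    end <- r[["start"]] + length(rev_rc) - 1L
    frag[[length(frag) + 1L]] <- data.frame(
      id = genes$id[i], length = end - f[["start"]] + 1L,
      start = f[["start"]], end = end, stringsAsFactors = FALSE)
  }
  fragments <- if (length(frag)) do.call(rbind, frag) else {
    data.frame(id = character(0), length = integer(0),
               start = integer(0), end = integer(0))
  }
  structure(list(fragments = fragments,
                 bands = .bin_bands(fragments$length, resolution),
                 resolution = resolution),
            class = "amplicon_profile")
}

.bin_bands <- function(lengths, resolution) {
  if (!length(lengths)) return(data.frame(band = numeric(0), n = integer(0)))
  x <- sort(lengths)
  grp <- cumsum(c(1L, as.integer(diff(x) > resolution)))
  bands <- vapply(split(x, grp), function(v) round(mean(v)), 0)
  data.frame(band = as.numeric(bands),
             n = as.integer(table(grp)), row.names = NULL)
}

#' @export
print.amplicon_profile <- function(x, ...) {
  cat(sprintf("Amplicon profile: %d fragments, %d bands (resolution %d bp)\n",
              nrow(x$fragments), nrow(x$bands), x$resolution))
  if (nrow(x$bands)) {
    cat("  bands (bp x n):",
        paste(sprintf("%gx%d", x$bands$band, x$bands$n), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two gene repertoires
#'
#' Partitions two repertoires by exact sequence identity into shared and
#' unique sets, and additionally reports pattern-level differences (element
#' patterns present in one repertoire and absent from the other).  By default
#' both repertoires must come from the same animal; cross-animal comparison
#' (used to confirm that genotypes share no sequences) requires
#' `cross_animal = TRUE`.
#'
#' @param a,b Lists with fields `animal`, `cell_class`, and `members`: a data
#'   frame with columns `sequence`, `pattern` (and optionally `variant`).
#' @param cross_animal Allow repertoires from different animals.
#' @return List with `shared`, `unique_a`, `unique_b` (character vectors of
#'   sequences), and `patterns_only_in_a`, `patterns_only_in_b`.
#' @export
compare_repertoires <- function(a, b, cross_animal = FALSE) {
  stopifnot(is.list(a), is.list(b),
            is.data.frame(a$members), is.data.frame(b$members))
  if (!cross_animal && !identical(a$animal, b$animal)) {
    .stopf("repertoires are from different animals (%s vs %s); set cross_animal = TRUE",
           a$animal, b$animal)
  }
  sa <- unique(a$members$sequence)
  sb <- unique(b$members$sequence)
  pa <- unique(a$members$pattern)
  pb <- unique(b$members$pattern)
  list(shared = intersect(sa, sb),
       unique_a = setdiff(sa, sb),
       unique_b = setdiff(sb, sa),
       patterns_only_in_a = setdiff(pa, pb),
       patterns_only_in_b = setdiff(pb, pa))
}

#' Relative gene copy number by the delta-delta-Ct method
#'
#' For a target gene, `dCT` in each sample is the target Cq minus the
#' reference-gene Cq; `ddCT` is the focal sample's dCT minus the reference
#' sample's; the copy ratio is `efficiency^(-ddCT)` (efficiency 2 assumes
#' perfect doubling per cycle).  A target undetected (absent) in the focal
#' sample yields an `ABSENT` result, rendered `"X"` in reports.  An absent
#' reference gene is an integrity error — normalisation is impossible.
#'
#' @param cq A `cq_table` (see [read_cq_table()]).
#' @param target Target gene name.
#' @param focal_sample,reference_sample Sample ids (e.g. a coelomocyte
#'   sample normalised against the same animal's sperm).
#' @param reference_target Reference (control) gene name; defaults to the
#'   table's attached reference.
#' @param efficiency Amplification efficiency (fold change per cycle).
#' @return List of class `copy_ratio`: `target`, `ratio` (numeric or `NA`
#'   when absent), `absent`, `dct_focal`, `dct_reference`, `ddct`.
#' @export
ddct_copy_ratio <- function(cq, target, focal_sample, reference_sample,
                            reference_target = attr(cq, "reference_target") %||% "SpGAPDH",
                            efficiency = 2) {
  stopifnot(is.data.frame(cq))
  get_cq <- function(sample, tgt) {
    i <- cq$sample_id == sample & cq$target == tgt
    if (!any(i)) .stopf("no Cq row for sample '%s', target '%s'", sample, tgt)
    cq$cq[which(i)[1]]
  }
  ref_f <- get_cq(focal_sample, reference_target)
  ref_r <- get_cq(reference_sample, reference_target)
  if (is.na(ref_f) || is.na(ref_r)) {
    .stopf("reference target '%s' absent; cannot normalise", reference_target)
  }
  t_f <- get_cq(focal_sample, target)
  t_r <- get_cq(reference_sample, target)
  if (is.na(t_f)) {
    return(structure(list(target = target, ratio = NA_real_, absent = TRUE,
                          dct_focal = NA_real_, dct_reference = t_r - ref_r,
                          ddct = NA_real_), class = "copy_ratio"))
  }
  if (is.na(t_r)) .stopf("target '%s' absent in reference sample '%s'", target, reference_sample)
  dct_f <- t_f - ref_f
  dct_r <- t_r - ref_r
  ddct <- dct_f - dct_r
  structure(list(target = target, ratio = efficiency^(-ddct), absent = FALSE,
                 dct_focal = dct_f, dct_reference = dct_r, ddct = ddct),
            class = "copy_ratio")
}

#' @export
print.copy_ratio <- function(x, ...) {
  cat(sprintf("%s: %s\n", x$target,
              if (x$absent) "X (absent)" else sprintf("ratio %.3g", x$ratio)))
  invisible(x)
}

#' Copy-ratio table for all targets of a focal sample
#'
#' @inheritParams ddct_copy_ratio
#' @param targets Character vector of target genes; default: all non-reference
#'   targets present in the focal or reference sample.
#' @return Data frame with columns `target`, `ratio` (numeric, `NA` absent)
#'   and `display` (ratio or `"X"`).
#' @export
ddct_copy_table <- function(cq, focal_sample, reference_sample,
                            targets = NULL,
                            reference_target = attr(cq, "reference_target") %||% "SpGAPDH",
                            efficiency = 2) {
  if (is.null(targets)) {
    targets <- setdiff(unique(cq$target[cq$sample_id %in% c(focal_sample, reference_sample)]),
                       reference_target)
  }
  res <- lapply(targets, function(t) {
    r <- ddct_copy_ratio(cq, t, focal_sample, reference_sample,
                         reference_target, efficiency)
    data.frame(target = t, ratio = r$ratio,
               display = if (r$absent) "X" else format(r$ratio, digits = 4),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Compare a focal amplicon profile against the germline profile
#'
#' Germline bands with no focal band within the profile resolution are
#' reported `missing` (the band-loss signature of somatic gene deletion);
#' focal-only bands are `novel`.
#'
#' @param focal,germline `amplicon_profile` objects from the same primer
#'   pair and resolution.
#' @return List with numeric vectors `missing` and `novel` (band lengths).
#' @export
missing_band_report <- function(focal, germline) {
  stopifnot(inherits(focal, "amplicon_profile"),
            inherits(germline, "amplicon_profile"))
  if (focal$resolution != germline$resolution) {
    .stopf("profiles have different resolutions (%d vs %d bp)",
           focal$resolution, germline$resolution)
  }
  res <- germline$resolution
  near <- function(x, set) length(set) > 0 && any(abs(set - x) <= res)
  gl <- germline$bands$band
  fc <- focal$bands$band
  list(missing = gl[!vapply(gl, near, TRUE, set = fc)],
       novel = fc[!vapply(fc, near, TRUE, set = gl)])
}
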