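#' Read nucleotide sequences from a FASTA file
#'
#' Reads plain or aligned FASTA into a data frame of sequence records.
#' Sequences are upper-cased on input.  By default only the unambiguous DNA
#' alphabet `A/C/G/T` is accepted; IUPAC ambiguity codes require
#' `tolerant = TRUE`, and alignment gaps (`-`) require `aligned = TRUE`.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; accept gap characters (`-`) in sequences.
#' @param tolerant Logical; accept IUPAC ambiguity codes beyond `A/C/G/T`.
#' @return A data frame with columns `id`, `sequence` and `description`
#'   (header text after the first whitespace), one row per record in file
#'   order.
#' @seealso [write_fasta()], [parse_seq_name()]
#' @export
read_fasta <- function(path, aligned = FALSE, tolerant = FALSE) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) .stopf("malformed FASTA in %s: %s", path, conditionMessage(e))
  )
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(headers))) {
    .stopf("malformed FASTA header (empty) in %s", path)
  }
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- NULL
  for (i in seq_along(seqs)) {
    .check_alphabet(seqs[i], ids[i], aligned = aligned, tolerant = tolerant)
  }
  data.frame(id = ids, sequence = seqs, description = desc,
             stringsAsFactors = FALSE)
}

.check_alphabet <- function(seq, id, aligned = FALSE, tolerant = FALSE) {
  if (!nzchar(seq)) .stopf("empty sequence for record '%s'", id)
  allowed <- .DNA
  if (aligned) allowed <- c(allowed, "-")
  if (tolerant) allowed <- c(allowed, setdiff(names(.IUPAC), .DNA))
  bad <- setdiff(unique(.chars(seq)), allowed)
  if (length(bad)) {
    .stopf("record '%s' contains disallowed symbol(s): %s", id,
           paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Write sequence records to FASTA
#'
#' @param records Data frame with columns `id`, `sequence` and optionally
#'   `description`, as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[i] %||% "")) paste(records$id[i], desc[i]) else records$id[i]
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# Sequence-name dialect ------------------------------------------------------

#' Parse a sequence name into its provenance tag
#'
#' Sequence names follow the dialect `<S|C|M><animal>-<pattern>-<variant>`,
#' e.g. `"S1-A3-2"`: source cell class (`S` sperm, `C` coelomocyte, `M` both),
#' animal number, element-pattern name, and sequence variant number within the
#' pattern.
#'
#' @param id A sequence name string.
#' @return A list of class `provenance_tag` with fields `source`
#'   (`"sperm"`, `"coelomocyte"` or `"both"`), `animal` (integer), `pattern`
#'   (character) and `variant` (integer).
#' @examples
#' parse_seq_name("S1-A3-2")
#' format_seq_name(parse_seq_name("M2-01-1"))
#' @export
parse_seq_name <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  m <- regmatches(id, regexec("^([SCM])([0-9]+)-([A-Za-z0-9]+)-([0-9]+)$", id))[[1]]
  if (length(m) != 5L) .stopf("sequence name '%s' does not match <S|C|M><animal>-<pattern>-<variant>", id)
  src <- c(S = "sperm", C = "coelomocyte", M = "both")[[m[2]]]
  structure(list(source = src, animal = as.integer(m[3]),
                 pattern = m[4], variant = as.integer(m[5])),
            class = "provenance_tag")
}

#' @rdname parse_seq_name
#' @param tag A `provenance_tag` as returned by `parse_seq_name()`.
#' @export
format_seq_name <- function(tag) {
  stopifnot(inherits(tag, "provenance_tag") || is.list(tag))
  letter <- c(sperm = "S", coelomocyte = "C", both = "M")[[tag$source]]
  sprintf("%s%d-%s-%d", letter, as.integer(tag$animal), tag$pattern,
          as.integer(tag$variant))
}

#' @export
print.provenance_tag <- function(x, ...) {
  cat(sprintf("<%s, animal %d, pattern %s, variant %d>\n",
              x$source, x$animal, x$pattern, x$variant))
  invisible(x)
}

# Cq tables ------------------------------------------------------------------

#' Read a qPCR Cq table from CSV
#'
#' The CSV must have columns `sample_id`, `cell_class`, `target`, `cq`.
#' Undetected targets (absent genes) are encoded by an empty `cq` cell or the
#' literal `"X"` and become `NA` in the returned table.  Every
#' `(sample_id, target)` pair must be unique and the reference target must be
#' present (with a numeric Cq) for every sample.
#'
#' @param path CSV path.
#' @param reference_target Name of the single-copy reference gene (the
#'   GAPDH-type control), required in every sample.
#' @return A data frame of class `cq_table` with columns `sample_id`,
#'   `cell_class`, `target`, `cq` (numeric cycles, `NA` = absent).
#' @export
read_cq_table <- function(path, reference_target = "SpGAPDH") {
  if (!file.exists(path)) .stopf("Cq table not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "cell_class", "target", "cq")
  if (!all(need %in% names(df))) {
    .stopf("Cq CSV must have columns: %s", paste(need, collapse = ", "))
  }
  cq <- trimws(df$cq)
  absent <- cq == "" | toupper(cq) == "X"
  val <- suppressWarnings(as.numeric(cq))
  if (any(!absent & is.na(val))) {
    .stopf("non-numeric cq value(s): %s",
           paste(unique(cq[!absent & is.na(val)]), collapse = ", "))
  }
  val[absent] <- NA_real_
  if (any(!is.na(val) & val <= 0)) .stopf("cq values must be positive cycles")
  out <- data.frame(sample_id = df$sample_id, cell_class = df$cell_class,
                    target = df$target, cq = val, stringsAsFactors = FALSE)
  validate_cq_table(out, reference_target)
}

#' @rdname read_cq_table
#' @param cq A data frame with the `cq_table` columns.
#' @export
validate_cq_table <- function(cq, reference_target = "SpGAPDH") {
  key <- paste(cq$sample_id, cq$target, sep = "\r")
  if (anyDuplicated(key)) {
    .stopf("duplicate (sample_id, target) pair(s): %s",
           paste(unique(gsub("\r", "/", key[duplicated(key)])), collapse = ", "))
  }
  bad <- unlist(lapply(split(cq, cq$sample_id), function(s) {
    i <- s$target == reference_target
    if (!any(i) || all(is.na(s$cq[i]))) s$sample_id[1] else character(0)
  }))
  if (length(bad)) {
    .stopf("reference target '%s' missing or absent for sample(s): %s",
           reference_target, paste(bad, collapse = ", "))
  }
  class(cq) <- c("cq_table", "data.frame")
  attr(cq, "reference_target") <- reference_target
  cq
}

#' Write a Cq table to CSV, rendering absent targets as "X"
#'
#' @param cq A `cq_table` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cq_table <- function(cq, path) {
  out <- as.data.frame(cq)[c("sample_id", "cell_class", "target", "cq")]
  out$cq <- ifelse(is.na(out$cq), "X", format(out$cq, trim = TRUE))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
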