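#' Element libraries and pattern catalogs
#'
#' A mosaic gene family is described by an ordered library of conserved
#' sequence blocks ("elements") and a catalog of named element patterns —
#' presence/absence vectors over the library.  Every family member is a
#' concatenation, in library order, of the elements its pattern marks present.
#'
#' @param elements Data frame with columns `index` (strictly increasing
#'   integers), `name` (unique), `consensus` (nucleotide string, >= 6 nt) and
#'   optionally `min_len`, `max_len` (defaults: consensus length).
#' @param patterns Named list; each entry is a character vector of element
#'   names (or logical vector over the library) marking present elements.
#' @return An object of class `element_library`: a list with `elements`
#'   (data frame) and `patterns` (logical matrix, patterns x elements).
#' @seealso [read_element_library()], [decompose_sequence()]
#' @export
element_library <- function(elements, patterns = list()) {
  stopifnot(is.data.frame(elements),
            all(c("index", "name", "consensus") %in% names(elements)))
  elements$index <- as.integer(elements$index)
  if (nrow(elements) == 0L) .stopf("element library must contain >= 1 element")
  if (any(diff(elements$index) <= 0)) .stopf("element indices must be strictly increasing")
  if (anyDuplicated(elements$name)) .stopf("element names must be unique")
  elements$consensus <- toupper(elements$consensus)
  if (any(nchar(elements$consensus) < 6L)) .stopf("element consensus must be >= 6 nt")
  for (i in seq_len(nrow(elements))) {
    .check_alphabet(elements$consensus[i], elements$name[i])
  }
  if (!"min_len" %in% names(elements)) elements$min_len <- nchar(elements$consensus)
  if (!"max_len" %in% names(elements)) elements$max_len <- nchar(elements$consensus)
  pm <- matrix(FALSE, nrow = length(patterns), ncol = nrow(elements),
               dimnames = list(names(patterns), elements$name))
  for (p in names(patterns)) {
    v <- patterns[[p]]
    if (is.logical(v)) {
      stopifnot(length(v) == nrow(elements))
      pm[p, ] <- v
    } else {
      unknown <- setdiff(v, elements$name)
      if (length(unknown)) .stopf("pattern '%s' uses unknown element(s): %s",
                                  p, paste(unknown, collapse = ", "))
      pm[p, v] <- TRUE
    }
    if (!any(pm[p, ])) .stopf("pattern '%s' has no present element", p)
  }
  if (anyDuplicated(rownames(pm))) .stopf("pattern names must be unique")
  structure(list(elements = elements, patterns = pm), class = "element_library")
}

#' @export
print.element_library <- function(x, ...) {
  cat(sprintf("Element library: %d elements, %d catalog patterns\n",
              nrow(x$elements), nrow(x$patterns)))
  cat("  elements:", paste(x$elements$name, collapse = " "), "\n")
  if (nrow(x$patterns)) {
    cat("  patterns:", paste(rownames(x$patterns), collapse = " "), "\n")
  }
  invisible(x)
}

#' Read or write an element library as JSON
#'
#' The JSON schema has two top-level keys: `elements`, an array of objects
#' with `index`, `name`, `consensus` (and optional `min_len`/`max_len`); and
#' `patterns`, an object mapping pattern names to arrays of element names.
#'
#' @param path JSON file path.
#' @return For `read_element_library()`, an `element_library`.
#' @export
read_element_library <- function(path) {
  if (!file.exists(path)) .stopf("element library not found: %s", path)
  j <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  patterns <- lapply(j$patterns, unlist)
  element_library(as.data.frame(j$elements), patterns)
}

#' @rdname read_element_library
#' @param lib An `element_library`.
#' @export
write_element_library <- function(lib, path) {
  stopifnot(inherits(lib, "element_library"))
  pat <- lapply(seq_len(nrow(lib$patterns)), function(i) {
    colnames(lib$patterns)[lib$patterns[i, ]]
  })
  names(pat) <- rownames(lib$patterns)
  jsonlite::write_json(list(elements = lib$elements, patterns = pat),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Load the packaged synthetic element library
#'
#' A small schematic library (10 elements, 12 named patterns) shipped for
#' examples and synthetic runs.  It mirrors the *structure* of the published
#' SpTrf element-pattern figure — pattern names and presence/absence layout —
#' but its consensus sequences are synthetic: the true element sequences are
#' defined in prior reference alignments and are supplied by the user for
#' real-data runs.
#'
#' @return An `element_library`.
#' @export
default_element_library <- function() {
  read_element_library(system.file("extdata", "synthetic_element_library.json",
                                   package = "mosaicdiv", mustWork = TRUE))
}
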