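#' Parse an NLM MeSH trees file
#'
#' Reads the plain ASCII "descriptor;tree-number" dialect of the NLM MeSH
#' Trees file (one line per descriptor/tree-number pair, e.g.
#' `"Heart;A07.541"`). A descriptor that occurs on several lines — MeSH
#' terms commonly occupy multiple positions in the hierarchy — is collapsed
#' into a single record carrying all of its tree numbers.
#'
#' Descriptor names are whitespace-trimmed; matching elsewhere in the
#' package is case-insensitive. Lines that do not contain a semicolon or
#' whose tree number does not look like a dot-separated MeSH code
#' (`A01.111.236` style) are skipped with a warning and counted in the
#' `n_skipped` attribute of the result.
#'
#' @param path Path to the trees file.
#' @return A data frame of class `mesh_terms` with columns `name`
#'   (descriptor), `tree_numbers` (list column of character vectors) and
#'   `max_depth` (largest number of dot-separated components over the
#'   term's tree numbers). Attribute `n_skipped` holds the count of
#'   malformed lines.
#' @export
#' @examples
#' tf <- tempfile()
#' writeLines(c("Heart;A07.541", "Heart;A07.231.114"), tf)
#' parse_mesh_trees(tf)
parse_mesh_trees <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read MeSH trees file: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  has_semi <- grepl(";", lines, fixed = TRUE)
  parts <- strsplit(lines[has_semi], ";", fixed = TRUE)
  name <- trimws(vapply(parts, `[`, "", 1L))
  tree <- trimws(vapply(parts, function(p) paste(p[-1L], collapse = ";"), ""))
  ok <- nzchar(name) & grepl("^[A-Z][0-9]+(\\.[0-9]+)*$", tree)

  n_skipped <- sum(!has_semi) + sum(!ok)
  if (n_skipped > 0L) {
    warning(n_skipped, " malformed line(s) skipped in ", path, call. = FALSE)
  }
  name <- name[ok]
  tree <- tree[ok]
  if (length(name) == 0L) {
    stop("no parseable descriptor;tree-number lines in ", path, call. = FALSE)
  }

  # aggregate tree numbers per descriptor, preserving first-seen order
  key <- tolower(name)
  first <- !duplicated(key)
  ord_names <- name[first]
  tn <- split(tree, factor(key, levels = key[first]))
  tn <- lapply(tn, unique)
  depth <- vapply(tn, function(x) max(lengths(strsplit(x, ".", fixed = TRUE))), 1L)

  out <- data.frame(name = ord_names, stringsAsFactors = FALSE)
  out$tree_numbers <- unname(tn)
  out$max_depth <- unname(depth)
  class(out) <- c("mesh_terms", "data.frame")
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter MeSH terms by hierarchy depth
#'
#' Keeps the descriptors whose position in the MeSH tree is deep enough to
#' be informative: a term qualifies when any of its tree numbers has at
#' least `min_components` dot-separated components (the top-level
#' letter-number code, e.g. `A01`, counts as component one). The default of
#' three reproduces the convention of only indexing terms with three or
#' more parent nodes; broader roots such as `A01` or `C14.280` are dropped.
#'
#' @param terms A `mesh_terms` data frame from [parse_mesh_trees()].
#' @param min_components Minimum component count (>= 1); default 3.
#' @return The filtered `mesh_terms` data frame, input order preserved.
#' @export
filter_terms_by_depth <- function(terms, min_components = 3L) {
  stopifnot(is.data.frame(terms), min_components >= 1L)
  out <- terms[terms$max_depth >= min_components, , drop = FALSE]
  rownames(out) <- NULL
  out
}

tree_depth <- function(tree_number) {
  lengths(strsplit(tree_number, ".", fixed = TRUE))
}
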