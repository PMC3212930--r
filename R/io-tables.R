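# Readers for the NCBI-dialect link tables consumed by the corpus and
# annotation builders. All are TAB-separated with an optional "#"-prefixed
# header line; parsing is strict about the columns the pipeline needs and
# tolerant of trailing extras.

read_tsv_body <- function(path, n_min_cols) {
  if (!file.exists(path)) stop("cannot read file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- lengths(fields) >= n_min_cols
  list(fields = fields[keep], n_skipped = sum(!keep))
}

#' Read a mesh2pubmed link table
#'
#' Two TAB-separated columns: MeSH descriptor name, PubMed ID. Lines whose
#' PMID is not a positive integer are skipped with a warning.
#'
#' @param path Path to the table.
#' @return Data frame with columns `term` (character) and `pubmed_id`
#'   (integer).
#' @export
read_mesh2pubmed <- function(path) {
  b <- read_tsv_body(path, 2L)
  term <- trimws(vapply(b$fields, `[`, "", 1L))
  pmid <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 2L)))
  ok <- nzchar(term) & !is.na(pmid) & pmid > 0L
  n_skipped <- b$n_skipped + sum(!ok)
  if (n_skipped > 0L) warning(n_skipped, " line(s) skipped in ", path, call. = FALSE)
  data.frame(term = term[ok], pubmed_id = pmid[ok], stringsAsFactors = FALSE)
}

#' Read an NCBI gene2pubmed-format table
#'
#' TAB-separated `tax_id`, `GeneID`, `PubMed_ID` with a "#" header line.
#'
#' @param path Path to the table.
#' @return Data frame with integer columns `tax_id`, `gene_id`, `pubmed_id`.
#' @export
read_gene2pubmed <- function(path) {
  b <- read_tsv_body(path, 3L)
  tax <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 1L)))
  gene <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 2L)))
  pmid <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 3L)))
  ok <- !is.na(tax) & !is.na(gene) & !is.na(pmid) & gene > 0L & pmid > 0L
  n_skipped <- b$n_skipped + sum(!ok)
  if (n_skipped > 0L) warning(n_skipped, " line(s) skipped in ", path, call. = FALSE)
  data.frame(tax_id = tax[ok], gene_id = gene[ok], pubmed_id = pmid[ok])
}

#' Read an NCBI homologene.data-format table
#'
#' TAB-separated; column 1 is the HomoloGene group ID, column 3 the GeneID.
#' Other columns are ignored. A GeneID listed under several groups keeps
#' its first group.
#'
#' @param path Path to the table.
#' @return Named integer vector mapping GeneID (names) to HomoloGene ID.
#' @export
read_homologene <- function(path) {
  b <- read_tsv_body(path, 3L)
  hid <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 1L)))
  gene <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 3L)))
  ok <- !is.na(hid) & !is.na(gene)
  if (b$n_skipped + sum(!ok) > 0L) {
    warning(b$n_skipped + sum(!ok), " line(s) skipped in ", path, call. = FALSE)
  }
  hid <- hid[ok]; gene <- gene[ok]
  first <- !duplicated(gene)
  stats::setNames(hid[first], gene[first])
}

#' Read an NCBI gene2go-format table
#'
#' TAB-separated with columns tax_id, GeneID, GO_ID, Evidence, Qualifier,
#' GO_term, PubMed, Category; Category is one of Process, Function,
#' Component.
#'
#' @param path Path to the table.
#' @return Data frame with columns `gene_id`, `go_id`, `go_term`, `aspect`.
#' @export
read_gene2go <- function(path) {
  b <- read_tsv_body(path, 8L)
  gene <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 2L)))
  go_id <- vapply(b$fields, `[`, "", 3L)
  go_term <- vapply(b$fields, `[`, "", 6L)
  aspect <- vapply(b$fields, `[`, "", 8L)
  ok <- !is.na(gene) & aspect %in% c("Process", "Function", "Component")
  n_skipped <- b$n_skipped + sum(!ok)
  if (n_skipped > 0L) warning(n_skipped, " line(s) skipped in ", path, call. = FALSE)
  data.frame(gene_id = gene[ok], go_id = go_id[ok], go_term = go_term[ok],
             aspect = aspect[ok], stringsAsFactors = FALSE)
}

#' Read a GeneRIF-style interactions table
#'
#' TAB-separated with columns gene_a, gene_b, source_db, pubmed_ids
#' (semicolon-joined, may be empty); extra trailing columns are tolerated.
#' Rows lacking a numeric GeneID on either side are skipped with a count.
#'
#' @param path Path to the table.
#' @return Data frame with columns `gene_a`, `gene_b`, `source_db`,
#'   `pubmed_ids` (character; semicolon-joined). Attribute `n_skipped`
#'   records discarded rows.
#' @export
read_interactions <- function(path) {
  b <- read_tsv_body(path, 3L)
  a <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 1L)))
  g <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 2L)))
  src <- vapply(b$fields, `[`, "", 3L)
  pm <- vapply(b$fields, function(f) if (length(f) >= 4L) f[4L] else "", "")
  ok <- !is.na(a) & !is.na(g)
  n_skipped <- b$n_skipped + sum(!ok)
  if (n_skipped > 0L) warning(n_skipped, " interaction row(s) skipped in ", path, call. = FALSE)
  out <- data.frame(gene_a = a[ok], gene_b = g[ok], source_db = src[ok],
                    pubmed_ids = pm[ok], stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Read a gene-to-pathway membership table
#'
#' TAB-separated columns gene_id, pathway_id, pathway_name (KEGG-style
#' identifiers, e.g. `hsa04110`).
#'
#' @param path Path to the table.
#' @return Data frame with columns `gene_id`, `pathway_id`, `pathway_name`.
#' @export
read_pathways <- function(path) {
  b <- read_tsv_body(path, 3L)
  gene <- suppressWarnings(as.integer(vapply(b$fields, `[`, "", 1L)))
  pid <- vapply(b$fields, `[`, "", 2L)
  pname <- vapply(b$fields, `[`, "", 3L)
  ok <- !is.na(gene) & nzchar(pid)
  if (b$n_skipped + sum(!ok) > 0L) {
    warning(b$n_skipped + sum(!ok), " line(s) skipped in ", path, call. = FALSE)
  }
  data.frame(gene_id = gene[ok], pathway_id = pid[ok], pathway_name = pname[ok],
             stringsAsFactors = FALSE)
}

#' Read a query gene list
#'
#' Plain text, one GeneID per line; "#" comments and blank lines ignored.
#'
#' @param path Path to the list.
#' @return Integer vector of unique GeneIDs.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("cannot read gene list: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- suppressWarnings(as.integer(lines))
  if (anyNA(ids)) {
    stop("non-numeric GeneID(s) in ", path, ": ",
         paste(utils::head(lines[is.na(ids)], 5L), collapse = ", "), call. = FALSE)
  }
  unique(ids)
}
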