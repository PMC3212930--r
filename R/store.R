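# On-disk store for a mesh_corpus: a directory of plain TSV tables plus a
# JSON manifest. Floating-point statistics are written with 17 significant
# digits so a save/load round trip reproduces every double bit-exactly.

fmt_dbl <- function(x) sprintf("%.17g", x)

#' Save a corpus database to a directory store
#'
#' Writes `terms.tsv`, `associations.tsv`, `stats.tsv`, `homologene.tsv`
#' and `manifest.json` (format version, row counts, build parameters) into
#' `dir`, creating it if needed.
#'
#' @param db A `mesh_corpus` object.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
save_corpus <- function(db, dir) {
  stopifnot(inherits(db, "mesh_corpus"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  terms <- data.frame(
    name = db$terms$name,
    tree_numbers = vapply(db$terms$tree_numbers, paste, "", collapse = ";"),
    max_depth = db$terms$max_depth
  )
  utils::write.table(terms, file.path(dir, "terms.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  assoc <- data.frame(
    term = db$associations$term,
    gene_id = db$associations$gene_id,
    pubmed_ids = vapply(db$associations$pubmed_ids, paste, "", collapse = ";")
  )
  utils::write.table(assoc, file.path(dir, "associations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  st <- data.frame(
    term = vapply(db$stats, `[[`, "", "term"),
    n_genes = vapply(db$stats, `[[`, 1L, "n_genes"),
    n_homologene = vapply(db$stats, `[[`, 1L, "n_homologene"),
    n_pubmed = vapply(db$stats, `[[`, 1L, "n_pubmed"),
    mean_citations = fmt_dbl(vapply(db$stats, `[[`, 1, "mean_citations")),
    sd_citations = fmt_dbl(vapply(db$stats, `[[`, 1, "sd_citations"))
  )
  utils::write.table(st, file.path(dir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  hom <- data.frame(gene_id = names(db$homologene),
                    homologene_id = unname(db$homologene))
  utils::write.table(hom, file.path(dir, "homologene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    format = "mesh_corpus-store",
    format_version = 1L,
    package_version = as.character(utils::packageVersion("meshenrich")),
    n_terms = nrow(db$terms),
    n_associations = nrow(db$associations),
    n_categories = length(db$stats),
    n_genes = length(db$gene_universe),
    params = db$params
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Load a corpus database from a directory store
#'
#' Inverse of [save_corpus()]. Citation-per-gene counts are reconstructed
#' from the association table; summary means and standard deviations are
#' read back from `stats.tsv` exactly as written.
#'
#' @param dir Store directory.
#' @return A `mesh_corpus` object.
#' @export
load_corpus <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop(dir, " is not a corpus store (missing manifest.json)", call. = FALSE)
  }
  manifest <- jsonlite::read_json(man_path, simplifyVector = TRUE)

  terms <- utils::read.delim(file.path(dir, "terms.tsv"),
                             colClasses = c("character", "character", "integer"))
  tn <- strsplit(terms$tree_numbers, ";", fixed = TRUE)
  terms <- data.frame(name = terms$name, stringsAsFactors = FALSE)
  terms$tree_numbers <- tn
  terms$max_depth <- vapply(tn, function(x) max(tree_depth(x)), 1L)
  class(terms) <- c("mesh_terms", "data.frame")

  assoc_raw <- utils::read.delim(file.path(dir, "associations.tsv"),
                                 colClasses = c("character", "integer", "character"))
  assoc <- data.frame(term = assoc_raw$term, gene_id = assoc_raw$gene_id,
                      stringsAsFactors = FALSE)
  assoc$pubmed_ids <- lapply(strsplit(assoc_raw$pubmed_ids, ";", fixed = TRUE),
                             as.integer)

  hom_df <- utils::read.delim(file.path(dir, "homologene.tsv"),
                              colClasses = c("character", "integer"))
  hom <- stats::setNames(hom_df$homologene_id, hom_df$gene_id)

  st <- utils::read.delim(file.path(dir, "stats.tsv"), colClasses = c(
    "character", "integer", "integer", "integer", "character", "character"))
  split_idx <- split(seq_len(nrow(assoc)),
                     factor(tolower(assoc$term), levels = tolower(st$term)))
  stats_list <- lapply(seq_len(nrow(st)), function(i) {
    idx <- split_idx[[i]]
    s <- list(
      term = st$term[i],
      n_genes = st$n_genes[i],
      n_homologene = st$n_homologene[i],
      n_pubmed = st$n_pubmed[i],
      citations_per_gene = stats::setNames(lengths(assoc$pubmed_ids[idx]),
                                           assoc$gene_id[idx]),
      mean_citations = as.numeric(st$mean_citations[i]),
      sd_citations = as.numeric(st$sd_citations[i])
    )
    class(s) <- "category_stats"
    s
  })
  names(stats_list) <- st$term

  db <- list(
    terms = terms,
    associations = assoc,
    stats = stats_list,
    gene_universe = sort(unique(assoc$gene_id)),
    homologene = hom,
    params = manifest$params
  )
  class(db) <- "mesh_corpus"
  db
}
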