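#' Join MeSH-literature and gene-literature links into gene-term associations
#'
#' For every (term, gene) pair that shares at least one PubMed ID between
#' the mesh2pubmed and gene2pubmed tables, emits one association carrying
#' the full set of shared PubMed IDs — the citations supporting that
#' gene-term link. Pairs with no shared citation are absent. The join is
#' insensitive to input row order.
#'
#' @param mesh2pubmed Data frame with columns `term`, `pubmed_id`
#'   (see [read_mesh2pubmed()]).
#' @param gene2pubmed Data frame with columns `tax_id`, `gene_id`,
#'   `pubmed_id` (see [read_gene2pubmed()]).
#' @param tax_filter Optional integer vector of taxonomy IDs; `NULL`
#'   (default) keeps all taxa.
#' @return Data frame with columns `term`, `gene_id` and list column
#'   `pubmed_ids` (sorted integer vectors), one row per gene-term pair.
#' @export
build_associations <- function(mesh2pubmed, gene2pubmed, tax_filter = NULL) {
  stopifnot(all(c("term", "pubmed_id") %in% names(mesh2pubmed)),
            all(c("tax_id", "gene_id", "pubmed_id") %in% names(gene2pubmed)))
  g2p <- gene2pubmed
  if (!is.null(tax_filter) && length(tax_filter) > 0L) {
    g2p <- g2p[g2p$tax_id %in% tax_filter, , drop = FALSE]
  }
  m2p <- unique(mesh2pubmed[c("term", "pubmed_id")])
  m2p$term <- trimws(m2p$term)
  g2p <- unique(g2p[c("gene_id", "pubmed_id")])

  joined <- merge(m2p, g2p, by = "pubmed_id")
  if (nrow(joined) == 0L) {
    warning("association join is empty", call. = FALSE)
    out <- data.frame(term = character(), gene_id = integer())
    out$pubmed_ids <- list()
    return(out)
  }
  key <- paste(tolower(joined$term), joined$gene_id, sep = "\r")
  ord <- order(tolower(joined$term), joined$gene_id, joined$pubmed_id)
  joined <- joined[ord, ]
  key <- key[ord]
  first <- !duplicated(key)
  out <- data.frame(term = joined$term[first], gene_id = joined$gene_id[first],
                    stringsAsFactors = FALSE)
  out$pubmed_ids <- unname(split(joined$pubmed_id, factor(key, levels = key[first])))
  rownames(out) <- NULL
  out
}

#' Per-category citation statistics
#'
#' For each MeSH term, tallies its unique genes, HomoloGene groups and
#' supporting PubMed IDs, and summarises citations per gene: the citation
#' count of a gene in a category is the number of distinct PubMed IDs
#' linking that gene to that term (not the gene's global literature
#' footprint). The mean and sample standard deviation (n - 1 divisor; 0
#' for single-gene categories) of these counts drive the `>Avg` and
#' `>StDev` stringency filters.
#'
#' @param associations Association data frame from [build_associations()].
#' @param homologene Named integer vector GeneID -> HomoloGene ID (may be
#'   empty).
#' @return Named list (one element per term) of `category_stats` records:
#'   `term`, `n_genes`, `n_homologene`, `n_pubmed`, `citations_per_gene`
#'   (named integer vector keyed by GeneID), `mean_citations`,
#'   `sd_citations`.
#' @export
compute_category_stats <- function(associations, homologene = integer()) {
  stopifnot(nrow(associations) > 0L)
  split_idx <- split(seq_len(nrow(associations)),
                     factor(tolower(associations$term),
                            levels = unique(tolower(associations$term))))
  out <- lapply(split_idx, function(idx) {
    genes <- associations$gene_id[idx]
    pm <- associations$pubmed_ids[idx]
    counts <- stats::setNames(lengths(pm), genes)
    hid <- homologene[as.character(genes)]
    s <- list(
      term = associations$term[idx[1L]],
      n_genes = length(genes),
      n_homologene = length(unique(hid[!is.na(hid)])),
      n_pubmed = length(unique(unlist(pm))),
      citations_per_gene = counts,
      mean_citations = mean(counts),
      sd_citations = if (length(counts) > 1L) stats::sd(counts) else 0
    )
    class(s) <- "category_stats"
    s
  })
  names(out) <- vapply(out, `[[`, "", "term")
  out
}

#' Build the gene-MeSH corpus database
#'
#' Runs the full construction pipeline: parse the MeSH trees file, drop
#' shallow terms (fewer than `min_depth` tree components), join the
#' literature link tables into gene-term associations, and compute
#' per-category citation statistics. Associations for terms absent from
#' the (filtered) tree file are discarded.
#'
#' @param trees Path to the MeSH trees file, or a `mesh_terms` data frame.
#' @param mesh2pubmed Path or data frame (see [read_mesh2pubmed()]).
#' @param gene2pubmed Path or data frame (see [read_gene2pubmed()]).
#' @param homologene Optional path or named vector (see
#'   [read_homologene()]).
#' @param min_depth Minimum tree-number component count; default 3.
#' @param tax_filter Optional taxonomy ID filter for gene2pubmed.
#' @return A `mesh_corpus` object: list with elements `terms`,
#'   `associations`, `stats`, `gene_universe`, `homologene`, `params`.
#' @export
build_corpus <- function(trees, mesh2pubmed, gene2pubmed, homologene = NULL,
                         min_depth = 3L, tax_filter = NULL) {
  terms <- if (is.character(trees)) parse_mesh_trees(trees) else trees
  terms <- filter_terms_by_depth(terms, min_depth)
  if (is.character(mesh2pubmed)) mesh2pubmed <- read_mesh2pubmed(mesh2pubmed)
  if (is.character(gene2pubmed)) gene2pubmed <- read_gene2pubmed(gene2pubmed)
  hom <- if (is.null(homologene)) {
    stats::setNames(integer(), character())
  } else if (is.character(homologene)) {
    read_homologene(homologene)
  } else homologene

  assoc <- build_associations(mesh2pubmed, gene2pubmed, tax_filter)
  known <- tolower(assoc$term) %in% tolower(terms$name)
  if (any(!known)) {
    message(sum(!known), " association row(s) reference terms outside the ",
            "filtered tree file and were dropped")
    assoc <- assoc[known, , drop = FALSE]
    rownames(assoc) <- NULL
  }
  stats <- if (nrow(assoc) > 0L) {
    compute_category_stats(assoc, hom)
  } else {
    structure(list(), names = character())
  }
  db <- list(
    terms = terms,
    associations = assoc,
    stats = stats,
    gene_universe = sort(unique(assoc$gene_id)),
    homologene = hom,
    params = list(min_depth = as.integer(min_depth),
                  tax_filter = tax_filter)
  )
  class(db) <- "mesh_corpus"
  db
}

#' @export
print.mesh_corpus <- function(x, ...) {
  s <- db_stats(x)
  cat("mesh_corpus:", s$n_terms_with_genes, "populated terms (of",
      nrow(x$terms), "in tree),", s$n_genes, "genes,",
      s$n_pubmed, "PubMed IDs,", s$n_top_level_categories_populated,
      "top-level categories\n")
  invisible(x)
}

#' Summary statistics of a corpus database
#'
#' Tallies what the interactive tool exposed as "DB Stats": populated MeSH
#' terms, top-level MeSH categories represented (distinct leading letters
#' of tree numbers of populated terms), HomoloGene groups, genes and
#' PubMed IDs.
#'
#' @param db A `mesh_corpus` object.
#' @return List with `n_terms_with_genes`,
#'   `n_top_level_categories_populated`, `n_homologene_ids`, `n_genes`,
#'   `n_pubmed`.
#' @export
db_stats <- function(db) {
  stopifnot(inherits(db, "mesh_corpus"))
  populated <- names(db$stats)
  if (length(populated) == 0L) {
    return(list(n_terms_with_genes = 0L, n_top_level_categories_populated = 0L,
                n_homologene_ids = 0L, n_genes = 0L, n_pubmed = 0L))
  }
  idx <- match(tolower(populated), tolower(db$terms$name))
  letters_seen <- unique(substr(unlist(db$terms$tree_numbers[idx]), 1L, 1L))
  hid <- db$homologene[as.character(db$gene_universe)]
  list(
    n_terms_with_genes = length(populated),
    n_top_level_categories_populated = length(letters_seen),
    n_homologene_ids = length(unique(hid[!is.na(hid)])),
    n_genes = length(db$gene_universe),
    n_pubmed = length(unique(unlist(db$associations$pubmed_ids)))
  )
}
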