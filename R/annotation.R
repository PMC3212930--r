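GO_ASPECTS <- c("Process", "Function", "Component")

#' Group genes by Gene Ontology term within one aspect
#'
#' Buckets the query genes by the GO terms annotating them in the
#' requested aspect (Biological Process, Molecular Function or Cellular
#' Component — the B/M/C views). A gene may fall in several buckets
#' (multi-annotation); genes with no annotation in the aspect are
#' collected under `"unannotated"` so the buckets always cover the query.
#'
#' @param genes Integer vector of GeneIDs.
#' @param annotations Data frame from [read_gene2go()] (columns `gene_id`,
#'   `go_id`, `go_term`, `aspect`).
#' @param aspect One of `"Process"`, `"Function"`, `"Component"`.
#' @return Named list of integer vectors (GO term name -> genes), with a
#'   final `"unannotated"` element when applicable. Attribute `sizes` is a
#'   data frame of bucket sizes for chart export.
#' @export
group_by_go <- function(genes, annotations, aspect = c("Process", "Function", "Component")) {
  aspect <- match.arg(aspect)
  genes <- unique(as.integer(genes))
  ann <- annotations[annotations$aspect == aspect &
                       annotations$gene_id %in% genes, , drop = FALSE]
  buckets <- lapply(split(ann$gene_id, ann$go_term), function(g) sort(unique(g)))
  covered <- unique(ann$gene_id)
  orphan <- setdiff(genes, covered)
  if (length(orphan) > 0L) buckets <- c(buckets, list(unannotated = sort(orphan)))
  sizes <- data.frame(go_term = names(buckets), n_genes = lengths(buckets),
                      stringsAsFactors = FALSE)
  rownames(sizes) <- NULL
  attr(buckets, "sizes") <- sizes
  buckets
}

#' Export GO bucket sizes as TSV and a static pie chart
#'
#' @param buckets Output of [group_by_go()].
#' @param path Image path (`.png` or `.svg`); the companion TSV uses the
#'   same stem.
#' @return List with `image` and `table` paths, invisibly.
#' @export
export_go_chart <- function(buckets, path) {
  sizes <- attr(buckets, "sizes")
  if (is.null(sizes) || nrow(sizes) == 0L) stop("empty GO grouping", call. = FALSE)
  open_device(path, 640L, 480L)
  graphics::pie(sizes$n_genes, labels = sizes$go_term)
  close_device()
  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  con <- file(tsv, "w")
  writeLines("#go_term\tn_genes", con)
  utils::write.table(sizes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(list(image = path, table = tsv))
}

#' Map genes to pathway buckets
#'
#' Assigns the query genes to their KEGG-style pathway memberships; a gene
#' on several pathways appears in each. Pathway identifiers are preserved
#' so users can open the corresponding diagram externally.
#'
#' @param genes Integer vector of GeneIDs.
#' @param memberships Data frame from [read_pathways()] (columns
#'   `gene_id`, `pathway_id`, `pathway_name`).
#' @return Named list of integer vectors (pathway id -> member genes);
#'   attribute `table` is a data frame with `pathway_id`, `pathway_name`
#'   and `n_genes`.
#' @export
map_to_pathways <- function(genes, memberships) {
  genes <- unique(as.integer(genes))
  mm <- memberships[memberships$gene_id %in% genes, , drop = FALSE]
  buckets <- lapply(split(mm$gene_id, mm$pathway_id), function(g) sort(unique(g)))
  name_of <- mm$pathway_name[match(names(buckets), mm$pathway_id)]
  tab <- data.frame(pathway_id = names(buckets), pathway_name = name_of,
                    n_genes = lengths(buckets), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(buckets, "table") <- tab
  buckets
}

#' Protein-interaction edges for a gene set
#'
#' Extracts the interaction edges touching the gene set. Interactions are
#' treated as undirected: `(a, b)` and `(b, a)` merge into one edge keyed
#' by the sorted pair, with source databases and supporting PMIDs
#' concatenated and a multiplicity count of contributing rows.
#' Self-interactions are dropped (with a logged count) as they carry no
#' pairwise information.
#'
#' @param genes Integer vector of GeneIDs.
#' @param edges Data frame from [read_interactions()].
#' @param within_only If `TRUE`, keep only edges with both endpoints in
#'   `genes`; if `FALSE` (default), keep edges with at least one endpoint
#'   in the set.
#' @return List with `edges` (data frame: `gene_a`, `gene_b`, `sources`,
#'   `pubmed_ids`, `n_records`; gene_a < gene_b) and `nodes` (data frame:
#'   `gene_id`, `degree`, `in_query`).
#' @export
interactions_for <- function(genes, edges, within_only = FALSE) {
  genes <- unique(as.integer(genes))
  self <- edges$gene_a == edges$gene_b
  if (any(self)) {
    message(sum(self), " self-interaction(s) dropped")
    edges <- edges[!self, , drop = FALSE]
  }
  lo <- pmin(edges$gene_a, edges$gene_b)
  hi <- pmax(edges$gene_a, edges$gene_b)
  keep <- if (within_only) {
    lo %in% genes & hi %in% genes
  } else {
    lo %in% genes | hi %in% genes
  }
  lo <- lo[keep]; hi <- hi[keep]
  src <- edges$source_db[keep]; pm <- edges$pubmed_ids[keep]

  key <- paste(lo, hi, sep = "-")
  ord <- order(lo, hi, src, method = "radix")
  lo <- lo[ord]; hi <- hi[ord]; src <- src[ord]; pm <- pm[ord]; key <- key[ord]
  first <- !duplicated(key)
  f <- factor(key, levels = key[first])
  merged <- data.frame(
    gene_a = lo[first],
    gene_b = hi[first],
    sources = vapply(split(src, f), function(s) paste(unique(s), collapse = ";"), ""),
    pubmed_ids = vapply(split(pm, f), function(p) {
      paste(unique(unlist(strsplit(p[nzchar(p)], ";", fixed = TRUE))), collapse = ";")
    }, ""),
    n_records = as.integer(lengths(split(src, f))),
    stringsAsFactors = FALSE
  )
  rownames(merged) <- NULL
  node_ids <- sort(unique(c(merged$gene_a, merged$gene_b)))
  nodes <- data.frame(
    gene_id = node_ids,
    degree = vapply(node_ids, function(g) {
      sum(merged$gene_a == g | merged$gene_b == g)
    }, 1L),
    in_query = node_ids %in% genes
  )
  list(edges = merged, nodes = nodes)
}

#' Export an interaction network for external viewers
#'
#' Writes the merged edge table as TSV and the network as GraphML (via
#' igraph), the standard exchange format for graph viewers.
#'
#' @param network Output of [interactions_for()].
#' @param edge_tsv Path for the TSV edge table.
#' @param graphml Optional path for the GraphML file.
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, edge_tsv, graphml = NULL) {
  con <- file(edge_tsv, "w")
  writeLines("#gene_a\tgene_b\tsources\tpubmed_ids\tn_records", con)
  if (nrow(network$edges) > 0L) {
    utils::write.table(network$edges, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  close(con)
  paths <- edge_tsv
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("gene_a", "gene_b", "sources", "n_records")],
      directed = FALSE,
      vertices = data.frame(name = as.character(network$nodes$gene_id),
                            in_query = network$nodes$in_query)
    )
    igraph::write_graph(g, graphml, format = "graphml")
    paths <- c(paths, graphml)
  }
  invisible(paths)
}
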