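# Seeded generators for every input dialect the package parses, with
# planted statistical structure (an enriched MeSH category, a shifted gene
# group, an interaction clique) recorded in a JSON truth file. One global
# seed drives a named pseudo-random stream per file type, so regenerating
# one file never perturbs the others.

stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}

#' Specification for a synthetic gene-MeSH corpus
#'
#' Describes the simulated literature: `n_genes` background genes,
#' `n_terms` MeSH-like categories with tree numbers drawn as random paths
#' of depth `tree_depth_range` under top-level branches A, C, D and G,
#' per-category membership sizes in `members_range`, and per (gene, term)
#' citation counts distributed 1 + Poisson(`lambda`) so every association
#' has at least one supporting article. `planted_terms` plants signal: each
#' entry names a term, its member count, and the fraction of the query set
#' drawn from its members; `query_size` genes form the query (drawn
#' uniformly from the universe when nothing is planted).
#'
#' @param n_genes Number of genes in the simulated universe (default 300).
#' @param n_terms Number of MeSH-like terms (default 40).
#' @param tree_depth_range Length-2 integer range of tree-number component
#'   counts (default `c(1, 5)`).
#' @param members_range Length-2 range of genes per background category
#'   (default `c(5, 25)`).
#' @param lambda Poisson rate for extra citations per gene-term pair
#'   (default 1).
#' @param planted_terms List of `list(term=, n_member_genes=,
#'   query_overlap_fraction=)` entries; default empty (null corpus).
#' @param query_size Query gene-set size (default 20).
#' @param seed Integer seed fixing all randomness.
#' @return A `corpus_spec` list.
#' @export
corpus_spec <- function(n_genes = 300L, n_terms = 40L,
                        tree_depth_range = c(1L, 5L),
                        members_range = c(5L, 25L), lambda = 1,
                        planted_terms = list(), query_size = 20L,
                        seed = 1L) {
  for (p in planted_terms) {
    stopifnot(p$n_member_genes <= n_genes,
              p$query_overlap_fraction >= 0, p$query_overlap_fraction <= 1)
    if (round(p$query_overlap_fraction * query_size) > p$n_member_genes) {
      stop("infeasible plant: overlap ", round(p$query_overlap_fraction * query_size),
           " exceeds member count ", p$n_member_genes, call. = FALSE)
    }
  }
  spec <- list(n_genes = as.integer(n_genes), n_terms = as.integer(n_terms),
               tree_depth_range = as.integer(tree_depth_range),
               members_range = as.integer(members_range), lambda = lambda,
               planted_terms = planted_terms,
               query_size = as.integer(query_size), seed = as.integer(seed))
  class(spec) <- "corpus_spec"
  spec
}

random_tree_number <- function(depth) {
  top <- paste0(sample(c("A", "C", "D", "G"), 1L),
                sprintf("%02d", sample.int(20L, 1L)))
  if (depth == 1L) return(top)
  paste(c(top, sprintf("%03d", sample.int(999L, depth - 1L, replace = TRUE))),
        collapse = ".")
}

#' Generate a synthetic corpus file bundle
#'
#' Writes, under `dir`: `mesh_trees.txt` (descriptor;tree-number lines),
#' `mesh2pubmed.tsv`, `gene2pubmed.tsv`, `homologene.data` and
#' `truth.json`. Every gene-term association is realised as that many
#' distinct PubMed IDs shared between the two link tables, so the join
#' reconstructs the planted memberships and citation counts exactly. The
#' truth record lists term depths, category memberships, planted terms and
#' the query gene set with its planted overlap.
#'
#' @param spec A [corpus_spec()].
#' @param dir Output directory (created if needed).
#' @return The truth record, invisibly; files are written under `dir`.
#' @export
generate_corpus <- function(spec, dir) {
  stopifnot(inherits(spec, "corpus_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- spec$seed

  planted_names <- vapply(spec$planted_terms, `[[`, "", "term")
  n_background <- spec$n_terms - length(planted_names)
  stopifnot(n_background >= 0L)
  term_names <- c(planted_names,
                  sprintf("Background Category %03d", seq_len(n_background)))

  terms <- with_stream(seed, "trees", {
    depth <- sample(spec$tree_depth_range[1L]:spec$tree_depth_range[2L],
                    spec$n_terms, replace = TRUE)
    # planted terms must survive the default depth filter
    if (length(planted_names) > 0L) {
      depth[seq_along(planted_names)] <- pmax(depth[seq_along(planted_names)], 3L)
    }
    n_extra <- stats::rbinom(spec$n_terms, 1L, 0.25)
    lapply(seq_len(spec$n_terms), function(i) {
      tn <- vapply(seq_len(1L + n_extra[i]), function(j) {
        random_tree_number(if (j == 1L) depth[i] else
          sample(spec$tree_depth_range[1L]:spec$tree_depth_range[2L], 1L))
      }, "")
      list(name = term_names[i], tree_numbers = unique(tn),
           max_depth = max(tree_depth(unique(tn))))
    })
  })

  genes <- 1000L + seq_len(spec$n_genes)
  membership <- with_stream(seed, "membership", {
    lapply(seq_len(spec$n_terms), function(i) {
      n_mem <- if (i <= length(planted_names)) {
        spec$planted_terms[[i]]$n_member_genes
      } else {
        sample(spec$members_range[1L]:spec$members_range[2L], 1L)
      }
      sort(sample(genes, n_mem))
    })
  })

  citations <- with_stream(seed, "citations", {
    lapply(membership, function(mem) 1L + stats::rpois(length(mem), spec$lambda))
  })

  # unique PMIDs per (term, gene, citation) triple keep the join exact
  pmid_counter <- 100000L
  mesh2pubmed <- list(); gene2pubmed <- list()
  for (i in seq_len(spec$n_terms)) {
    mem <- membership[[i]]
    for (j in seq_along(mem)) {
      pmids <- pmid_counter + seq_len(citations[[i]][j])
      pmid_counter <- pmid_counter + citations[[i]][j]
      mesh2pubmed[[length(mesh2pubmed) + 1L]] <-
        data.frame(term = term_names[i], pubmed_id = pmids)
      gene2pubmed[[length(gene2pubmed) + 1L]] <-
        data.frame(tax_id = 9606L, gene_id = mem[j], pubmed_id = pmids)
    }
  }
  mesh2pubmed <- do.call(rbind, mesh2pubmed)
  gene2pubmed <- do.call(rbind, gene2pubmed)

  homologene <- with_stream(seed, "homologene", {
    covered <- sort(sample(genes, round(0.7 * length(genes))))
    data.frame(hid = 5000L + seq_along(covered), covered = covered)
  })

  query <- with_stream(seed, "query", {
    if (length(planted_names) > 0L) {
      p <- spec$planted_terms[[1L]]
      n_in <- round(p$query_overlap_fraction * spec$query_size)
      inside <- sample(membership[[1L]], n_in)
      outside_pool <- setdiff(genes, membership[[1L]])
      outside <- sample(outside_pool, spec$query_size - n_in)
      sort(c(inside, outside))
    } else {
      sort(sample(genes, spec$query_size))
    }
  })

  tree_lines <- unlist(lapply(terms, function(t) {
    paste0(t$name, ";", t$tree_numbers)
  }))
  writeLines(tree_lines, file.path(dir, "mesh_trees.txt"))

  write_link_table <- function(df, path, header) {
    con <- file(path, "w")
    writeLines(header, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  write_link_table(mesh2pubmed, file.path(dir, "mesh2pubmed.tsv"),
                   "#term\tPubMed_ID")
  write_link_table(gene2pubmed, file.path(dir, "gene2pubmed.tsv"),
                   "#tax_id\tGeneID\tPubMed_ID")
  hom_df <- data.frame(hid = homologene$hid, tax = 9606L,
                       gene = homologene$covered,
                       symbol = paste0("GENE", homologene$covered))
  utils::write.table(hom_df, file.path(dir, "homologene.data"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  truth <- list(
    seed = seed,
    n_genes = spec$n_genes,
    genes = genes,
    terms = lapply(seq_len(spec$n_terms), function(i) {
      list(name = term_names[i],
           tree_numbers = terms[[i]]$tree_numbers,
           max_depth = terms[[i]]$max_depth,
           members = membership[[i]],
           citations = citations[[i]])
    }),
    planted_terms = planted_names,
    query = query,
    query_overlap = if (length(planted_names) > 0L) {
      length(intersect(query, membership[[1L]]))
    } else 0L
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Specification for a synthetic expression matrix
#'
#' Two sample groups of equal size; planted genes receive a between-group
#' mean shift of `effect` log2 units on top of Gaussian noise with
#' standard deviation `noise_sd`; background genes shift zero.
#'
#' @param n_probes Number of probes (default 200).
#' @param n_samples Total samples, split into two equal groups (default
#'   12; must be an even number >= 2).
#' @param effect Planted between-group log2 shift (default 2).
#' @param noise_sd Gaussian noise standard deviation in log2 units
#'   (default 0.5).
#' @param baseline Baseline log2 intensity (default 8).
#' @param seed Integer seed.
#' @return An `expression_spec` list.
#' @export
expression_spec <- function(n_probes = 200L, n_samples = 12L, effect = 2,
                            noise_sd = 0.5, baseline = 8, seed = 1L) {
  stopifnot(n_samples >= 2L, n_samples %% 2L == 0L)
  spec <- list(n_probes = as.integer(n_probes), n_samples = as.integer(n_samples),
               effect = effect, noise_sd = noise_sd, baseline = baseline,
               seed = as.integer(seed))
  class(spec) <- "expression_spec"
  spec
}

#' Generate a synthetic expression CSV and probe annotation
#'
#' Writes `expression.csv` (probe rows, log2 intensities, two groups of
#' samples named `ctrl_*` / `case_*`) and `annotation.tsv` (probe_id,
#' gene_id). Probes cycle over the truth record's genes; probes whose gene
#' belongs to the truth's first planted term carry the planted shift in
#' the case group.
#'
#' @param spec An [expression_spec()].
#' @param truth Truth record from [generate_corpus()].
#' @param dir Output directory.
#' @return List with `planted_probes`, `group` labels and the file paths,
#'   invisibly.
#' @export
generate_expression <- function(spec, truth, dir) {
  stopifnot(inherits(spec, "expression_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- as.integer(unlist(truth$genes))
  probe_gene <- genes[((seq_len(spec$n_probes) - 1L) %% length(genes)) + 1L]
  probe_ids <- sprintf("probe_%04d", seq_len(spec$n_probes))
  planted_genes <- if (length(truth$planted_terms) > 0L) {
    as.integer(unlist(truth$terms[[1L]]$members))
  } else integer()
  planted <- probe_gene %in% planted_genes

  half <- spec$n_samples %/% 2L
  group <- rep(c("ctrl", "case"), each = half)
  samples <- c(sprintf("ctrl_%02d", seq_len(half)),
               sprintf("case_%02d", seq_len(half)))

  m <- with_stream(spec$seed, "expression", {
    noise <- matrix(stats::rnorm(spec$n_probes * spec$n_samples,
                                 sd = spec$noise_sd),
                    nrow = spec$n_probes)
    base <- matrix(spec$baseline, spec$n_probes, spec$n_samples)
    base[planted, group == "case"] <- base[planted, group == "case"] + spec$effect
    base + noise
  })
  dimnames(m) <- list(probe_ids, samples)

  em <- new_expr_matrix(m)
  write_expression_csv(em, file.path(dir, "expression.csv"))
  ann <- data.frame(probe_id = probe_ids, gene_id = probe_gene,
                    gene_symbol = paste0("GENE", probe_gene))
  utils::write.table(ann, file.path(dir, "annotation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(list(planted_probes = probe_ids[planted], group = group,
                 expression = file.path(dir, "expression.csv"),
                 annotation = file.path(dir, "annotation.tsv")))
}

#' Generate synthetic annotation files (GO, interactions, pathways)
#'
#' Writes `gene2go.tsv`, `interactions.tsv` and `pathways.tsv` under
#' `dir`. Every gene of the truth's first planted term (or, lacking
#' plants, every universe gene) receives at least one GO term in each of
#' the three aspects; a designated subset of `clique_size` genes forms a
#' complete interaction clique (listed in the return value); pathway
#' membership assigns genes round-robin to toy pathway ids.
#'
#' @param truth Truth record from [generate_corpus()].
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param clique_size Size of the planted interaction clique (default 4).
#' @return List with `clique` (GeneIDs) and the file paths, invisibly.
#' @export
generate_annotation_files <- function(truth, dir, seed = 1L, clique_size = 4L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- as.integer(unlist(truth$genes))
  focus <- if (length(truth$planted_terms) > 0L) {
    as.integer(unlist(truth$terms[[1L]]$members))
  } else genes
  stopifnot(clique_size >= 2L, clique_size <= length(focus))

  go <- with_stream(seed, "gene2go", {
    rows <- list()
    for (aspect in GO_ASPECTS) {
      n_terms <- 6L
      go_ids <- sprintf("GO:%07d", match(aspect, GO_ASPECTS) * 100000L + seq_len(n_terms))
      go_names <- paste(tolower(aspect), "term", seq_len(n_terms))
      pick <- sample.int(n_terms, length(focus), replace = TRUE)
      rows[[aspect]] <- data.frame(
        tax_id = 9606L, gene_id = focus, go_id = go_ids[pick],
        evidence = "IEA", qualifier = "-", go_term = go_names[pick],
        pubmed = "-", category = aspect, stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  utils::write.table(go, file.path(dir, "gene2go.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  clique <- sort(focus[seq_len(clique_size)])
  pairs <- utils::combn(clique, 2L)
  inter <- with_stream(seed, "interactions", {
    extra_n <- min(30L, length(genes) %/% 4L)
    extra_a <- sample(genes, extra_n, replace = TRUE)
    extra_b <- sample(genes, extra_n, replace = TRUE)
    data.frame(
      gene_a = c(pairs[1L, ], extra_a),
      gene_b = c(pairs[2L, ], extra_b),
      source_db = sample(c("BioGRID", "BIND", "HPRD"),
                         ncol(pairs) + extra_n, replace = TRUE),
      pubmed_ids = "", stringsAsFactors = FALSE)
  })
  utils::write.table(inter, file.path(dir, "interactions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  pw_ids <- sprintf("hsa%05d", 4000L + seq_len(5L))
  pw <- data.frame(
    gene_id = focus,
    pathway_id = pw_ids[((seq_along(focus) - 1L) %% 5L) + 1L],
    pathway_name = paste("Toy pathway", ((seq_along(focus) - 1L) %% 5L) + 1L),
    stringsAsFactors = FALSE)
  utils::write.table(pw, file.path(dir, "pathways.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)

  invisible(list(clique = clique,
                 gene2go = file.path(dir, "gene2go.tsv"),
                 interactions = file.path(dir, "interactions.tsv"),
                 pathways = file.path(dir, "pathways.tsv")))
}

#' Read a truth record written by [generate_corpus()]
#'
#' @param path Path to `truth.json`.
#' @return The truth record as nested lists (no vector simplification, so
#'   structure matches what the generator returned).
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
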