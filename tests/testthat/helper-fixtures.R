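# Shared fixture builders. Everything is generated in code at test time;
# nothing is read from checked-in data files.

# tiny two-gene category used throughout: gene 7 cites {1,2,3}, gene 8
# cites {4} -> mean 2, sample sd sqrt(2)
tiny_assoc <- function() {
  a <- data.frame(term = c("T1", "T1"), gene_id = c(7L, 8L),
                  stringsAsFactors = FALSE)
  a$pubmed_ids <- list(c(1L, 2L, 3L), 4L)
  a
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# generate a corpus bundle and build the database from its files
build_fixture_db <- function(seed, planted = TRUE, dir = tempfile(),
                             n_genes = 300L, n_terms = 40L,
                             query_size = 20L, overlap = 0.8) {
  plants <- if (planted) {
    list(list(term = "Planted Signal Category", n_member_genes = 30L,
              query_overlap_fraction = overlap))
  } else list()
  spec <- corpus_spec(n_genes = n_genes, n_terms = n_terms,
                      planted_terms = plants, query_size = query_size,
                      seed = seed)
  truth <- generate_corpus(spec, dir)
  db <- suppressMessages(build_corpus(
    file.path(dir, "mesh_trees.txt"),
    file.path(dir, "mesh2pubmed.tsv"),
    file.path(dir, "gene2pubmed.tsv"),
    file.path(dir, "homologene.data")
  ))
  list(db = db, truth = truth, dir = dir)
}

# independent oracle: upper-tail hypergeometric probability by exhaustive
# enumeration of all size-n subsets of a 1:N universe whose first K
# elements are the category
hyper_tail_enum <- function(N, K, n, k) {
  if (k == 0) return(1)
  if (n == 0) return(0)
  subsets <- utils::combn(N, n)
  hits <- colSums(subsets <= K) >= k
  mean(hits)
}
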