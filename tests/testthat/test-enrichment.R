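test_that("hypergeom_tail matches its closed-form examples", {
  expect_identical(hypergeom_tail(10, 4, 3, 0), 1)
  expect_equal(hypergeom_tail(10, 4, 3, 2), 40 / 120, tolerance = 1e-12)
  expect_equal(hypergeom_tail(50, 50, 7, 7), 1, tolerance = 1e-12)
  expect_error(hypergeom_tail(10, 11, 3, 1), "invalid contingency")
  expect_error(hypergeom_tail(10, 4, 3, 4), "invalid contingency")
})

test_that("hypergeom_tail agrees with subset enumeration on a small grid", {
  for (N in c(5L, 8L)) {
    for (K in 0:N) for (n in 0:N) for (k in 0:min(n, K)) {
      expect_equal(hypergeom_tail(N, K, n, k), hyper_tail_enum(N, K, n, k),
                   tolerance = 1e-12,
                   label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
    }
  }
})

test_that("hypergeom_tail agrees with the survival-function cross-check", {
  set.seed(99)
  for (i in 1:200) {
    N <- sample(20:2000, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_tail(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("hypergeom_tail is monotone in k and in K", {
  N <- 40L; K <- 12L; n <- 10L
  p_k <- vapply(0:min(n, K), function(k) hypergeom_tail(N, K, n, k), 1)
  expect_true(all(diff(p_k) <= 1e-15))
  k <- 3L
  p_K <- vapply(k:(N - n + k), function(K) hypergeom_tail(N, K, n, k), 1)
  expect_true(all(diff(p_K) >= -1e-15))
})

test_that("stringency filters follow the worked citation fixture", {
  st <- compute_category_stats(tiny_assoc())[["T1"]]  # A=3, B=1 citations
  expect_setequal(apply_stringency(st, "unfiltered"), c(7L, 8L))
  expect_equal(apply_stringency(st, "gt_avg"), 7L)        # 3 > 2, 1 <= 2
  expect_equal(apply_stringency(st, "gt_stdev"), integer())  # 3 <= 2+sqrt(2)
})

test_that("stringency gene sets are nested for every generated category", {
  for (seed in 1:5) {
    fx <- build_fixture_db(seed, planted = (seed %% 2 == 0))
    for (st in fx$db$stats) {
      unf <- apply_stringency(st, "unfiltered")
      avg <- apply_stringency(st, "gt_avg")
      sdv <- apply_stringency(st, "gt_stdev")
      expect_true(all(sdv %in% avg))
      expect_true(all(avg %in% unf))
    }
  }
})

test_that("enrich scores a planted category first and reports the contract columns", {
  fx <- build_fixture_db(21)
  res <- enrich(unlist(fx$truth$query), fx$db)
  expect_s3_class(res, "mesh_enrichment")
  expect_true(all(c("term", "tree_numbers", "N", "K", "n", "k", "p_value",
                    "matched_gene_ids", "n_genes_total", "n_homologene")
                  %in% names(res)))
  expect_equal(res$term[1], "Planted Signal Category")
  expect_true(all(res$k >= 1))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_equal(res$N[1], length(fx$db$gene_universe))
  # |matched_genes| = k
  expect_equal(lengths(strsplit(res$matched_gene_ids, ";")), res$k)
  # descending sort reverses the p-value order
  res_d <- enrich(unlist(fx$truth$query), fx$db, sort = "desc")
  expect_equal(sort(res$p_value), sort(res_d$p_value))
  expect_true(all(diff(res_d$p_value) <= 1e-15))
})

test_that("enrich is deterministic and permutation-stable", {
  fx <- build_fixture_db(22)
  q <- unlist(fx$truth$query)
  r1 <- enrich(q, fx$db)
  r2 <- enrich(rev(q), fx$db)
  expect_identical(r1, r2)
})

test_that("enrich handles subtree restriction and unmapped queries", {
  fx <- build_fixture_db(23)
  res_all <- enrich(unlist(fx$truth$query), fx$db)
  prefix <- substr(strsplit(res_all$tree_numbers[1], ";")[[1]][1], 1, 1)
  res_sub <- enrich(unlist(fx$truth$query), fx$db, subtree = prefix)
  expect_true(all(grepl(paste0("(^|;)", prefix), res_sub$tree_numbers)))
  expect_lte(nrow(res_sub), nrow(res_all))
  # a prefix absent from the corpus names the valid ones
  expect_error(enrich(unlist(fx$truth$query), fx$db, subtree = "Z"),
               "valid top-level prefixes")
  # entirely unmapped query is fatal and reports the genes
  expect_error(enrich(c(1L, 2L), fx$db), "unmapped")
  # partially mapped query drops the stray gene from n
  q <- c(unlist(fx$truth$query), 999999L)
  res <- enrich(q, fx$db)
  expect_equal(res$n[1], length(intersect(q, fx$db$gene_universe)))
  expect_setequal(attr(res, "unmapped"), setdiff(q, fx$db$gene_universe))
  expect_true(999999L %in% attr(res, "unmapped"))
})

test_that("single-category membership yields a single k=1 result", {
  m2p <- data.frame(term = "Lonely", pubmed_id = 101L)
  g2p <- data.frame(tax_id = 9606L, gene_id = c(7L, 8L),
                    pubmed_id = c(101L, 102L))
  trees <- write_lines_tmp("Lonely;A01.100.200")
  db <- build_corpus(trees, m2p, g2p)
  res <- enrich(7L, db)
  expect_equal(nrow(res), 1L)
  expect_equal(res$k, 1L)
})

test_that("stringency filtering restricts both K and k", {
  # category {7, 8}; gene 7 has 3 citations, gene 8 one -> gt_avg keeps 7
  m2p <- data.frame(term = rep("T1", 4), pubmed_id = c(1L, 2L, 3L, 4L))
  g2p <- data.frame(tax_id = 9606L, gene_id = c(7L, 7L, 7L, 8L),
                    pubmed_id = c(1L, 2L, 3L, 4L))
  trees <- write_lines_tmp("T1;A01.100.200")
  db <- build_corpus(trees, m2p, g2p)
  res_unf <- enrich(c(7L, 8L), db, mode = "unfiltered")
  expect_equal(res_unf$K, 2L); expect_equal(res_unf$k, 2L)
  res_avg <- enrich(c(7L, 8L), db, mode = "gt_avg")
  expect_equal(res_avg$K, 1L); expect_equal(res_avg$k, 1L)
  expect_equal(res_avg$matched_gene_ids, "7")
})

test_that("optional FDR column is a Benjamini-Hochberg adjustment", {
  fx <- build_fixture_db(24)
  res <- enrich(unlist(fx$truth$query), fx$db, fdr = TRUE)
  expect_equal(res$fdr, stats::p.adjust(res$p_value, method = "BH"))
})

test_that("background restriction shrinks the universe consistently", {
  fx <- build_fixture_db(25)
  bg <- fx$db$gene_universe[seq_len(150)]
  q <- intersect(unlist(fx$truth$query), bg)
  skip_if(length(q) == 0)
  res <- enrich(q, fx$db, background = bg)
  expect_true(all(res$N == length(intersect(fx$db$gene_universe, bg))))
  expect_true(all(res$K <= res$N))
})

test_that("search_by_phrase is a case-insensitive substring lookup", {
  m2p <- data.frame(term = c("Asthma, Exercise-Induced", "Heart Failure"),
                    pubmed_id = c(101L, 102L))
  g2p <- data.frame(tax_id = 9606L, gene_id = c(7L, 8L),
                    pubmed_id = c(101L, 102L))
  trees <- write_lines_tmp(c("Asthma, Exercise-Induced;C08.127.108.054",
                             "Heart Failure;C14.280.434"))
  db <- build_corpus(trees, m2p, g2p)
  hit <- search_by_phrase("asthma", db)
  expect_equal(hit$term, "Asthma, Exercise-Induced")
  expect_equal(hit$gene_ids[[1]], 7L)
  expect_identical(search_by_phrase("ASTHMA", db)$term,
                   search_by_phrase("asthma", db)$term)
  expect_equal(nrow(search_by_phrase("no such term", db)), 0L)
})

test_that("query size limit warns without rejecting", {
  expect_silent(check_query_size(seq_len(499)))
  expect_warning(check_query_size(seq_len(500)), "500")
  expect_warning(check_query_size(seq_len(11), limit = 10L), "11 genes")
})

test_that("enrichment TSV export round-trips the result table", {
  fx <- build_fixture_db(26)
  res <- enrich(unlist(fx$truth$query), fx$db)
  f <- tempfile(fileext = ".tsv")
  write_enrichment(res, f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "#term\t"))
  expect_equal(length(lines) - 1L, nrow(res))
  back <- utils::read.delim(f, comment.char = "", check.names = FALSE)
  expect_equal(sub("^#", "", names(back)[1]), "term")
})
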