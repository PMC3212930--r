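#' Stringency modes for citation filtering
#'
#' The three levels of the citation-stringency pull-down: `"unfiltered"`
#' keeps every gene of a category; `"gt_avg"` keeps genes whose
#' per-category citation count strictly exceeds the category mean;
#' `"gt_stdev"` keeps genes strictly above mean plus one sample standard
#' deviation.
#'
#' @format Character vector of the three mode names.
#' @export
STRINGENCY_MODES <- c("unfiltered", "gt_avg", "gt_stdev")

#' Apply a citation-stringency filter to a category
#'
#' @param stats A `category_stats` record (one element of
#'   [compute_category_stats()] output).
#' @param mode One of [STRINGENCY_MODES].
#' @return Integer vector of the GeneIDs that pass the filter.
#' @export
#' @examples
#' a <- data.frame(term = "T1", gene_id = c(7L, 8L))
#' a$pubmed_ids <- list(1:3, 4L)
#' st <- compute_category_stats(a)[["T1"]]
#' apply_stringency(st, "gt_avg")   # gene 7 only: 3 > 2
apply_stringency <- function(stats, mode = c("unfiltered", "gt_avg", "gt_stdev")) {
  mode <- match.arg(mode)
  counts <- stats$citations_per_gene
  keep <- switch(mode,
    unfiltered = rep(TRUE, length(counts)),
    gt_avg = counts > stats$mean_citations,
    gt_stdev = counts > stats$mean_citations + stats$sd_citations
  )
  as.integer(names(counts)[keep])
}

#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` category genes when `n` genes are
#' sampled without replacement from a universe of `N` genes of which `K`
#' belong to the category:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)} \frac{\binom{K}{i}
#'   \binom{N-K}{n-i}}{\binom{N}{n}}.}
#' Terms are accumulated from log-scale binomial coefficients
#' (`lchoose`) so large universes do not overflow. `k = 0` returns
#' exactly 1.
#'
#' @param N Universe size.
#' @param K Category size (K <= N).
#' @param n Sample (query) size (n <= N).
#' @param k Observed overlap (0 <= k <= min(n, K)).
#' @return The tail probability, a value in (0, 1].
#' @export
#' @examples
#' hypergeom_tail(10, 4, 3, 2)  # = 40/120
hypergeom_tail <- function(N, K, n, k) {
  if (length(N) != 1L || length(K) != 1L || length(n) != 1L || length(k) != 1L ||
      anyNA(c(N, K, n, k))) {
    stop("N, K, n, k must be single non-missing numbers", call. = FALSE)
  }
  if (K > N || n > N || k < 0 || k > min(n, K)) {
    stop("invalid contingency counts: need K <= N, n <= N, 0 <= k <= min(n, K)",
         call. = FALSE)
  }
  if (k == 0) return(1)
  i <- k:min(n, K)
  log_terms <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(log_terms)
  p <- exp(m) * sum(exp(log_terms - m))
  min(p, 1)
}

#' Size check for query gene sets
#'
#' The enrichment workflow is intended for differentially expressed gene
#' sets of fewer than 500 genes; larger queries are legal (whole-array
#' analyses are supported) but trigger a warning.
#'
#' @param query Vector of GeneIDs.
#' @param limit Warning threshold; default 500.
#' @return `TRUE` (ok) or `FALSE` (over limit), invisibly; warns when over.
#' @export
check_query_size <- function(query, limit = 500L) {
  if (length(query) >= limit) {
    warning("query has ", length(query), " genes (>= ", limit,
            "); intended for differentially expressed sets below that size",
            call. = FALSE)
    return(invisible(FALSE))
  }
  invisible(TRUE)
}

#' MeSH-category over-representation analysis of a gene set
#'
#' Scores every populated MeSH category (optionally restricted to a
#' subtree) for over-representation of the query genes with the upper-tail
#' hypergeometric test. Under a stringency filter the category membership
#' is first restricted to genes passing the filter; both the category size
#' `K` and the overlap `k` use the filtered membership. The background
#' universe `N` defaults to all genes in the association database and can
#' be restricted with `background` (e.g. all genes on the platform).
#'
#' @param query Integer vector of GeneIDs.
#' @param db A `mesh_corpus` object.
#' @param mode One of [STRINGENCY_MODES]; default `"unfiltered"`.
#' @param subtree Optional tree-number prefix (e.g. `"C"` or `"C14.280"`);
#'   only terms having a tree number with that prefix are tested.
#' @param sort `"asc"` (default) or `"desc"` ordering by p-value; ties are
#'   broken by descending overlap then term name.
#' @param background Optional integer vector restricting the universe; the
#'   query and every category are intersected with it.
#' @param fdr If `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column (raw hypergeometric p-values are always reported).
#' @param size_limit Query-size warning threshold (see
#'   [check_query_size()]).
#' @return Data frame of class `mesh_enrichment` with one row per category
#'   having overlap k >= 1: columns `term`, `tree_numbers`, `N`, `K`, `n`,
#'   `k`, `p_value`, (`fdr`,) `matched_gene_ids` (semicolon-joined),
#'   `n_genes_total`, `n_homologene`. Attribute `unmapped` lists query
#'   genes absent from the universe.
#' @export
enrich <- function(query, db, mode = c("unfiltered", "gt_avg", "gt_stdev"),
                   subtree = NULL, sort = c("asc", "desc"),
                   background = NULL, fdr = FALSE, size_limit = 500L) {
  stopifnot(inherits(db, "mesh_corpus"))
  mode <- match.arg(mode)
  sort <- match.arg(sort)
  query <- unique(as.integer(query))
  check_query_size(query, size_limit)

  universe <- db$gene_universe
  if (!is.null(background)) universe <- intersect(universe, as.integer(background))
  unmapped <- setdiff(query, universe)
  query <- intersect(query, universe)
  if (length(query) == 0L) {
    stop("no query gene maps to the background universe; unmapped: ",
         paste(utils::head(unmapped, 10L), collapse = ", "),
         if (length(unmapped) > 10L) ", ..." else "", call. = FALSE)
  }

  terms_tested <- names(db$stats)
  term_idx <- match(tolower(terms_tested), tolower(db$terms$name))
  tree_nums <- db$terms$tree_numbers[term_idx]
  if (!is.null(subtree)) {
    hit <- if (grepl("^[A-Z]$", subtree)) {
      # a bare letter addresses a whole top-level MeSH category
      vapply(tree_nums, function(tn) any(substr(tn, 1L, 1L) == subtree), TRUE)
    } else {
      vapply(tree_nums, function(tn) {
        any(tn == subtree | startsWith(tn, paste0(subtree, ".")))
      }, TRUE)
    }
    if (!any(hit)) {
      valid <- sort(unique(substr(unlist(tree_nums), 1L, 1L)))
      stop("no populated term under subtree '", subtree,
           "'; valid top-level prefixes: ", paste(valid, collapse = ", "),
           call. = FALSE)
    }
    terms_tested <- terms_tested[hit]
    tree_nums <- tree_nums[hit]
  }

  N <- length(universe)
  n <- length(query)
  rows <- vector("list", length(terms_tested))
  for (i in seq_along(terms_tested)) {
    st <- db$stats[[terms_tested[i]]]
    members <- intersect(apply_stringency(st, mode), universe)
    K <- length(members)
    matched <- intersect(query, members)
    k <- length(matched)
    if (k == 0L) next
    rows[[i]] <- data.frame(
      term = st$term,
      tree_numbers = paste(tree_nums[[i]], collapse = ";"),
      N = N, K = K, n = n, k = k,
      p_value = hypergeom_tail(N, K, n, k),
      matched_gene_ids = paste(sort(matched), collapse = ";"),
      n_genes_total = st$n_genes,
      n_homologene = st$n_homologene,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(term = character(), tree_numbers = character(),
                      N = integer(), K = integer(), n = integer(),
                      k = integer(), p_value = numeric(),
                      matched_gene_ids = character(),
                      n_genes_total = integer(), n_homologene = integer(),
                      stringsAsFactors = FALSE)
  }
  if (fdr && nrow(out) > 0L) {
    out$fdr <- stats::p.adjust(out$p_value, method = "BH")
    out <- out[c("term", "tree_numbers", "N", "K", "n", "k", "p_value",
                 "fdr", "matched_gene_ids", "n_genes_total", "n_homologene")]
  }
  ord <- order(out$p_value, -out$k, out$term,
               decreasing = c(sort == "desc", FALSE, FALSE), method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- unmapped
  attr(out, "mode") <- mode
  class(out) <- c("mesh_enrichment", "data.frame")
  out
}

#' Find MeSH categories by word or phrase
#'
#' Returns the categories whose descriptor name contains the given phrase
#' as a case-insensitive substring, together with their associated gene
#' sets — the browsing feature for questions like "which genes are linked
#' to asthma?". No expression data is required.
#'
#' @param phrase Non-empty search string.
#' @param db A `mesh_corpus` object.
#' @return Data frame with columns `term` and list column `gene_ids`;
#'   zero rows when nothing matches.
#' @export
search_by_phrase <- function(phrase, db) {
  stopifnot(inherits(db, "mesh_corpus"), nzchar(trimws(phrase)))
  hits <- grepl(tolower(trimws(phrase)), tolower(names(db$stats)), fixed = TRUE)
  terms <- names(db$stats)[hits]
  out <- data.frame(term = vapply(db$stats[terms], `[[`, "", "term"),
                    stringsAsFactors = FALSE)
  out$gene_ids <- lapply(db$stats[terms], function(s) {
    as.integer(names(s$citations_per_gene))
  })
  rownames(out) <- NULL
  out
}

#' Write an enrichment result table as TSV
#'
#' Single "#"-prefixed header line, then one TAB-separated row per
#' category.
#'
#' @param result A `mesh_enrichment` data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(result), collapse = "\t")), con)
  if (nrow(result) > 0L) {
    df <- result
    df$p_value <- fmt_dbl(df$p_value)
    if ("fdr" %in% names(df)) df$fdr <- fmt_dbl(df$fdr)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
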