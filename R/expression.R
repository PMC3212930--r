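#' Read a probe-level expression CSV
#'
#' Expects the microarray export layout: first column probe identifiers, a
#' header row of sample names, remaining cells log2 intensity values.
#' Empty cells and the tokens `NA`/`NaN` are treated as missing; any other
#' non-numeric token aborts with the offending row/column coordinates so
#' corrupt files are not silently coerced. Duplicated probe identifiers
#' are fatal.
#'
#' @param path CSV file path.
#' @return An `expr_matrix` object: list with `values` (probes x samples
#'   numeric matrix, `NA` for missing), `probe_ids`, `sample_ids`,
#'   `probe2gene` (named integer vector, empty until [map_probes()]) and
#'   `flags` (per-probe character annotations).
#' @export
read_expression_csv <- function(path) {
  if (!file.exists(path)) stop("cannot read expression CSV: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  if (ncol(raw) < 2L) {
    stop("expression CSV needs a probe column plus at least one sample column",
         call. = FALSE)
  }
  probes <- trimws(raw[[1L]])
  dup <- unique(probes[duplicated(probes)])
  if (length(dup) > 0L) {
    stop("duplicate probe id(s) in ", path, ": ",
         paste(utils::head(dup, 10L), collapse = ", "), call. = FALSE)
  }
  samples <- colnames(raw)[-1L]
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  cells_trim <- trimws(cells)
  missing <- cells_trim == "" | toupper(cells_trim) %in% c("NA", "NAN")
  vals <- suppressWarnings(as.numeric(cells_trim))
  bad <- !missing & is.na(vals)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", cells[bad][1L], "' at row ", idx[1L],
         " (probe ", probes[idx[1L]], "), column '", samples[idx[2L]], "'",
         call. = FALSE)
  }
  vals[missing] <- NA_real_
  m <- matrix(vals, nrow = length(probes), ncol = length(samples),
              dimnames = list(probes, samples))
  new_expr_matrix(m)
}

new_expr_matrix <- function(values, probe2gene = NULL, flags = NULL) {
  x <- list(
    values = values,
    probe_ids = rownames(values),
    sample_ids = colnames(values),
    probe2gene = if (is.null(probe2gene)) stats::setNames(integer(), character()) else probe2gene,
    flags = if (is.null(flags)) {
      stats::setNames(rep("", nrow(values)), rownames(values))
    } else flags
  )
  class(x) <- "expr_matrix"
  x
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "probes x", ncol(x$values), "samples;",
      length(x$probe2gene), "probes mapped to GeneIDs\n")
  invisible(x)
}

#' Write an expression matrix back to CSV
#'
#' Inverse of [read_expression_csv()]; finite values round-trip
#' bit-exactly (17 significant digits), missing cells are written as `NA`.
#'
#' @param matrix An `expr_matrix` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_expression_csv <- function(matrix, path) {
  m <- matrix$values
  chr <- ifelse(is.na(m), "NA", sprintf("%.17g", m))
  df <- data.frame(probe_id = rownames(m), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("probe_id", colnames(m))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Attach probe-to-gene annotation
#'
#' Populates the probe-to-GeneID map from a platform annotation table
#' (TSV: probe_id, gene_id, optional gene_symbol). Probes without
#' annotation are retained and flagged `unmapped`; probe rows are never
#' collapsed to gene level, so several probes may share one GeneID.
#'
#' @param matrix An `expr_matrix` object.
#' @param annotation Path to the annotation TSV, or a data frame with
#'   columns `probe_id` and `gene_id`.
#' @return The annotated `expr_matrix`; a mapped/unmapped tally is
#'   reported via `message()`.
#' @export
map_probes <- function(matrix, annotation) {
  if (is.character(annotation)) {
    b <- read_tsv_body(annotation, 2L)
    annotation <- data.frame(
      probe_id = vapply(b$fields, `[`, "", 1L),
      gene_id = suppressWarnings(as.integer(vapply(b$fields, `[`, "", 2L))),
      stringsAsFactors = FALSE
    )
    annotation <- annotation[!is.na(annotation$gene_id), , drop = FALSE]
  }
  map <- stats::setNames(as.integer(annotation$gene_id), annotation$probe_id)
  map <- map[!duplicated(names(map))]
  hit <- matrix$probe_ids %in% names(map)
  matrix$probe2gene <- map[matrix$probe_ids[hit]]
  matrix$flags[!hit] <- trimws(paste(matrix$flags[!hit], "unmapped"))
  message(sum(hit), "/", length(hit), " probes mapped to GeneIDs")
  if (!any(hit)) warning("no probe could be mapped to a GeneID", call. = FALSE)
  matrix
}

#' Z-score normalize expression rows
#'
#' Transforms each probe row to `(x - mean) / sd` across samples, using
#' the sample standard deviation (n - 1 divisor). Missing cells are
#' excluded from the row mean and sd and stay missing; rows with zero
#' variance become all zeros and are flagged `constant`. Display on a
#' common per-probe scale is what makes multi-gene heatmaps comparable.
#'
#' @param matrix An `expr_matrix` with at least two samples.
#' @return The transformed `expr_matrix`.
#' @export
zscore_rows <- function(matrix) {
  m <- matrix$values
  if (ncol(m) < 2L) stop("z-score requires at least 2 samples", call. = FALSE)
  mu <- rowMeans(m, na.rm = TRUE)
  sdv <- apply(m, 1L, stats::sd, na.rm = TRUE)
  const <- !is.na(sdv) & sdv == 0
  z <- (m - mu) / sdv
  z[const, ] <- 0
  z[is.na(m)] <- NA_real_
  matrix$values <- z
  matrix$flags[const] <- trimws(paste(matrix$flags[const], "constant"))
  matrix
}

resolve_keys <- function(matrix, keys) {
  keys <- as.character(keys)
  gene_of_probe <- matrix$probe2gene
  hit <- lapply(keys, function(k) {
    probes <- matrix$probe_ids[matrix$probe_ids == k]
    gp <- names(gene_of_probe)[as.character(gene_of_probe) == k]
    unique(c(probes, gp))
  })
  names(hit) <- keys
  hit
}

#' View intensity values for probes or genes
#'
#' Returns the matrix rows matching any of the given keys, where a key may
#' be a probe identifier or a GeneID (resolved through the probe
#' annotation; a GeneID measured by several probes returns all of them).
#'
#' @param matrix An `expr_matrix` object.
#' @param keys Character or integer vector of probe IDs and/or GeneIDs.
#' @return Data frame with `probe_id`, `gene_id` and one column per
#'   sample. Attribute `unmatched` lists keys that resolved to nothing.
#' @export
view_intensity <- function(matrix, keys) {
  stopifnot(length(keys) > 0L)
  res <- resolve_keys(matrix, keys)
  unmatched <- names(res)[lengths(res) == 0L]
  probes <- unique(unlist(res))
  m <- matrix$values[probes, , drop = FALSE]
  gid <- unname(matrix$probe2gene[probes])
  out <- data.frame(probe_id = probes, gene_id = as.integer(gid),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(m, optional = TRUE))
  rownames(out) <- NULL
  attr(out, "unmatched") <- unmatched
  out
}

#' Render a heatmap of Z-scored intensities
#'
#' Draws the classic expression heatmap: the selected probes (or all
#' probes measuring the selected genes) are z-score normalized and
#' rendered row-per-probe, column-per-sample. With `cluster = TRUE` rows
#' (and columns) are ordered by hierarchical clustering with Euclidean
#' distance and average linkage. The plotted numeric submatrix is always
#' written alongside the image as a TSV so the rendering is auditable.
#'
#' @param matrix An `expr_matrix` object.
#' @param keys Probe IDs and/or GeneIDs selecting the rows; `NULL` plots
#'   all probes.
#' @param path Output image path; format from the extension (`.png` or
#'   `.svg`).
#' @param cluster Logical; hierarchically cluster rows and columns
#'   (default `TRUE`).
#' @param zscore Logical; z-score rows before plotting (default `TRUE`).
#' @return List with `image` (path), `table` (companion TSV path) and
#'   `row_order` (plotted probe order), invisibly.
#' @export
render_heatmap <- function(matrix, keys = NULL, path, cluster = TRUE,
                           zscore = TRUE) {
  if (is.null(keys)) {
    probes <- matrix$probe_ids
  } else {
    res <- resolve_keys(matrix, keys)
    probes <- unique(unlist(res))
    if (length(probes) == 0L) {
      stop("no matrix row matches the requested ids: ",
           paste(utils::head(names(res)[lengths(res) == 0L], 10L),
                 collapse = ", "), call. = FALSE)
    }
  }
  sub <- matrix
  sub$values <- matrix$values[probes, , drop = FALSE]
  sub$probe_ids <- probes
  sub$flags <- matrix$flags[probes]
  if (zscore) sub <- zscore_rows(sub)
  m <- sub$values

  can_cluster <- cluster && nrow(m) > 1L && !anyNA(m)
  if (can_cluster) {
    hc_r <- stats::hclust(stats::dist(m, method = "euclidean"),
                          method = "average")
    row_order <- rownames(m)[hc_r$order]
  } else {
    row_order <- rownames(m)
  }

  open_device(path, width = max(480L, 60L * ncol(m) + 160L),
              height = max(320L, 14L * nrow(m) + 140L))
  ok <- try(pheatmap::pheatmap(
    m,
    cluster_rows = can_cluster,
    cluster_cols = can_cluster && ncol(m) > 1L,
    clustering_distance_rows = "euclidean",
    clustering_distance_cols = "euclidean",
    clustering_method = "average",
    scale = "none",
    silent = TRUE
  ), silent = TRUE)
  if (!inherits(ok, "try-error")) grid::grid.draw(ok$gtable)
  close_device()

  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  out_m <- m[row_order, , drop = FALSE]
  df <- data.frame(probe_id = rownames(out_m), out_m, check.names = FALSE)
  con <- file(tsv, "w")
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(list(image = path, table = tsv, row_order = row_order))
}

# png() needs a raster backend; prefer cairo where compiled in.
open_device <- function(path, width = 640L, height = 480L) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height,
                         type = if (capabilities("cairo")) "cairo" else "Xlib"),
    svg = grDevices::svg(path, width = width / 96, height = height / 96),
    stop("unsupported image format '", ext, "' (use .png or .svg)",
         call. = FALSE)
  )
}

close_device <- function() {
  invisible(grDevices::dev.off())
}

#' Render a labeled dotplot
#'
#' One dot per labeled value, drawn with [graphics::dotchart()]. Duplicate
#' labels are suffixed (`.1`, `.2`, ...) with a warning so each dot is
#' addressable. A companion TSV of the plotted numbers is always written.
#'
#' @param values Named numeric vector.
#' @param path Output image path (`.png` or `.svg`).
#' @return List with `image` and `table` paths, invisibly.
#' @export
render_dotplot <- function(values, path) {
  if (length(values) == 0L) stop("no values to plot", call. = FALSE)
  labels <- names(values)
  if (is.null(labels)) labels <- as.character(seq_along(values))
  if (anyDuplicated(labels)) {
    warning("duplicate labels suffixed to be unique", call. = FALSE)
    labels <- make.unique(labels)
  }
  open_device(path, width = 640L, height = max(320L, 18L * length(values) + 120L))
  graphics::dotchart(unname(values), labels = labels, xlab = "value")
  close_device()

  tsv <- paste0(tools::file_path_sans_ext(path), ".tsv")
  con <- file(tsv, "w")
  writeLines("#label\tvalue", con)
  utils::write.table(data.frame(labels, fmt_dbl(unname(values))), con,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  close(con)
  invisible(list(image = path, table = tsv))
}
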