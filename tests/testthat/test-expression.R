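make_csv <- function(lines) write_lines_tmp(lines, ext = ".csv")

test_that("read_expression_csv parses well-formed matrices", {
  f <- make_csv(c("probe,s1,s2", "p1,1.5,2.5", "p2,0.0,-1.25", "p3,3,4"))
  em <- read_expression_csv(f)
  expect_equal(dim(em$values), c(3L, 2L))
  expect_equal(em$probe_ids, c("p1", "p2", "p3"))
  expect_equal(em$sample_ids, c("s1", "s2"))
  expect_equal(em$values["p2", "s2"], -1.25)
})

test_that("read_expression_csv flags missing cells and rejects corruption", {
  f <- make_csv(c("probe,s1,s2", "p1,NA,2", "p2,,3", "p3,NaN,4"))
  em <- read_expression_csv(f)
  expect_true(is.na(em$values["p1", "s1"]))
  expect_true(is.na(em$values["p2", "s1"]))
  expect_true(is.na(em$values["p3", "s1"]))

  f <- make_csv(c("probe,s1,s2", "p1,1,2", "p1,3,4"))
  expect_error(read_expression_csv(f), "p1")

  f <- make_csv(c("probe,s1,s2", "p1,1,2", "p2,oops,4"))
  expect_error(read_expression_csv(f), "oops")

  f <- make_csv(c("probe", "p1"))
  expect_error(read_expression_csv(f), "at least one sample")
})

test_that("expression CSV write/read round trip is bit-exact", {
  set.seed(31)
  m <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  m[2, 3] <- NA
  em <- meshenrich:::new_expr_matrix(m)
  f <- tempfile(fileext = ".csv")
  write_expression_csv(em, f)
  back <- read_expression_csv(f)
  expect_identical(back$values, m)
})

test_that("map_probes annotates without collapsing probes", {
  f <- make_csv(c("probe,s1,s2", "p1,1,2", "p2,3,4", "p3,5,6"))
  em <- read_expression_csv(f)
  ann <- data.frame(probe_id = c("p1", "p2"), gene_id = c(7L, 7L))
  expect_message(em <- map_probes(em, ann), "2/3")
  expect_equal(unname(em$probe2gene[c("p1", "p2")]), c(7L, 7L))
  expect_match(em$flags["p3"], "unmapped")
  # gene-level lookup returns both probes
  vi <- view_intensity(em, 7L)
  expect_setequal(vi$probe_id, c("p1", "p2"))

  expect_warning(
    suppressMessages(map_probes(em, data.frame(probe_id = character(),
                                               gene_id = integer()))),
    "no probe")
})

test_that("zscore_rows matches hand values and flags constant rows", {
  m <- rbind(p1 = c(1, 2, 3), p2 = c(5, 5, 5))
  colnames(m) <- paste0("s", 1:3)
  em <- meshenrich:::new_expr_matrix(m)
  z <- zscore_rows(em)
  expect_equal(unname(z$values["p1", ]), c(-1, 0, 1))
  expect_equal(unname(z$values["p2", ]), c(0, 0, 0))
  expect_match(z$flags["p2"], "constant")
  expect_error(zscore_rows(meshenrich:::new_expr_matrix(m[, 1, drop = FALSE])),
               "at least 2 samples")
})

test_that("zscore identities hold on randomized matrices", {
  for (seed in 1:20) {
    set.seed(seed)
    m <- matrix(rnorm(8 * 6, sd = runif(1, 0.5, 3)), 8, 6,
                dimnames = list(paste0("p", 1:8), paste0("s", 1:6)))
    em <- meshenrich:::new_expr_matrix(m)
    z <- zscore_rows(em)
    expect_true(all(abs(rowMeans(z$values)) < 1e-12))
    expect_true(all(abs(apply(z$values, 1, sd) - 1) < 1e-12))
    # idempotence
    z2 <- zscore_rows(z)
    expect_equal(z2$values, z$values, tolerance = 1e-9)
    # invariance under positive affine per-row transforms
    a <- runif(1, 0.1, 5); b <- rnorm(1, sd = 10)
    em_t <- meshenrich:::new_expr_matrix(a * m + b)
    expect_equal(zscore_rows(em_t)$values, z$values, tolerance = 1e-9)
  }
})

test_that("zscore_rows excludes missing cells but keeps them missing", {
  m <- rbind(p1 = c(1, 2, 3, NA))
  colnames(m) <- paste0("s", 1:4)
  z <- zscore_rows(meshenrich:::new_expr_matrix(m))
  expect_true(is.na(z$values["p1", "s4"]))
  expect_equal(unname(z$values["p1", 1:3]), c(-1, 0, 1))
})

test_that("view_intensity resolves probes, genes and reports unmatched keys", {
  f <- make_csv(c("probe,s1,s2", "p1,1,2", "p2,3,4"))
  em <- suppressMessages(map_probes(read_expression_csv(f),
                                    data.frame(probe_id = "p1", gene_id = 7L)))
  tab <- view_intensity(em, c("p2", "7", "nope"))
  expect_setequal(tab$probe_id, c("p1", "p2"))
  expect_equal(attr(tab, "unmatched"), "nope")
})

test_that("render_heatmap writes an auditable companion TSV", {
  set.seed(41)
  m <- matrix(rnorm(24), 6, 4,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:4)))
  em <- meshenrich:::new_expr_matrix(m)
  img <- tempfile(fileext = ".png")
  out <- render_heatmap(em, keys = c("p1", "p2", "p3"), path = img,
                        cluster = FALSE)
  expect_true(file.exists(out$image))
  expect_true(file.exists(out$table))
  # clustering off: row order equals request order
  expect_equal(out$row_order, c("p1", "p2", "p3"))
  tab <- utils::read.delim(out$table, comment.char = "", header = TRUE)
  expect_equal(nrow(tab), 3L)
  # companion TSV holds the z-scored values
  z <- zscore_rows(em)$values[c("p1", "p2", "p3"), ]
  expect_equal(as.matrix(tab[, -1]), unname(z), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(render_heatmap(em, keys = "absent", path = img), "absent")
})

test_that("clustered heatmaps place identical rows adjacently", {
  set.seed(42)
  base <- rnorm(5)
  m <- rbind(a = rnorm(5, 10), twin1 = base, b = rnorm(5, -4), twin2 = base,
             c = rnorm(5, 4))
  colnames(m) <- paste0("s", 1:5)
  em <- meshenrich:::new_expr_matrix(m)
  out <- render_heatmap(em, path = tempfile(fileext = ".png"),
                        cluster = TRUE, zscore = FALSE)
  pos <- match(c("twin1", "twin2"), out$row_order)
  expect_equal(abs(diff(pos)), 1L)
})

test_that("render_dotplot writes image plus TSV and uniquifies labels", {
  vals <- c(a = 1.5, b = -2, a = 0.25)
  img <- tempfile(fileext = ".png")
  expect_warning(out <- render_dotplot(vals, img), "duplicate")
  expect_true(file.exists(out$image))
  tab <- utils::read.delim(out$table, comment.char = "", header = TRUE)
  expect_equal(nrow(tab), 3L)
  expect_equal(anyDuplicated(tab[[1]]), 0L)

  single <- render_dotplot(c(only = 2), tempfile(fileext = ".png"))
  expect_true(file.exists(single$image))
  expect_error(render_dotplot(numeric(), tempfile(fileext = ".png")), "no values")
})
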