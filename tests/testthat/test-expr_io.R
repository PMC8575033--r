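# Reading, validation, filtering, imputation and normalization of
# expression matrices.

write_tsv_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("delimited parsing preserves ids, missing cells and orientation", {
  path <- write_tsv_fixture(c("sample_id\tG1\tG2",
                              "S1\t1.5\t2",
                              "S2\t\t0.25",
                              "S3\t3\t4"))
  em <- read_expression(path, "genes_in_columns")
  expect_equal(em$gene_ids, c("G1", "G2"))
  expect_equal(em$sample_ids, c("S1", "S2", "S3"))
  expect_equal(sum(is.na(em$values)), 1L)
  expect_true(is.na(em$values["S2", "G1"]))
  expect_equal(em$values["S3", "G2"], 4)

  # the same table declared gene-major reads as the transpose
  path2 <- write_tsv_fixture(c("gene_id\tS1\tS2\tS3",
                               "G1\t1.5\t\t3",
                               "G2\t2\t0.25\t4"))
  em2 <- read_expression(path2, "genes_in_rows")
  expect_equal(em2$values, em$values)
})

test_that("duplicate ids, negative values and ragged rows are hard errors", {
  dup <- write_tsv_fixture(c("id\tS1\tS2", "G1\t1\t2", "G1\t3\t4"))
  expect_error(read_expression(dup, "genes_in_rows"), "G1")
  neg <- write_tsv_fixture(c("id\tG1", "S1\t-2"))
  expect_error(read_expression(neg), "G1")
  ragged <- write_tsv_fixture(c("id\tG1\tG2", "S1\t1\t2", "S2\t3"))
  expect_error(read_expression(ragged))
})

test_that("gene filter removes chrY, all-zero and high-NA genes per rule", {
  set.seed(1)
  v <- matrix(runif(10 * 4, 0.1, 2), 10, 4)
  v[, 2] <- 0                      # all-zero gene
  v[1:2, 3] <- NA                  # 20% missing > 10%
  em <- expression_matrix(v, gene_ids = c("G_Y", "G_0", "G_na", "G_ok"))
  ann <- gene_annotation(c("G_Y", "G_0", "G_na", "G_ok"),
                         c("chrY", "chr1", "chr2", "chr3"))
  out <- filter_genes(em, ann)
  expect_equal(out$matrix$gene_ids, "G_ok")
  st <- setNames(out$report$status, out$report$gene_id)
  expect_equal(st[["G_Y"]], "removed_chrY")
  expect_equal(st[["G_0"]], "removed_all_zero")
  expect_equal(st[["G_na"]], "removed_na")
  # the report partitions the original gene universe
  expect_equal(sum(table(out$report$status)), n_genes(em))
})

test_that("a gene missing in exactly the threshold fraction is retained", {
  v <- matrix(1, 10, 2)
  v[1, 1] <- NA                     # exactly 10%
  em <- expression_matrix(v, gene_ids = c("Gborder", "Gfull"))
  out <- filter_genes(em, na_fraction_max = 0.1)
  expect_true("Gborder" %in% out$matrix$gene_ids)
  v[2, 1] <- NA                     # 20% now
  em2 <- expression_matrix(v, gene_ids = c("Gborder", "Gfull"))
  expect_false("Gborder" %in% filter_genes(em2)$matrix$gene_ids)
})

test_that("unannotated genes are retained and flagged, never dropped", {
  em <- expression_matrix(matrix(runif(6, 0.1, 1), 3, 2),
                          gene_ids = c("Gknown", "Gmystery"))
  ann <- gene_annotation("Gknown", "chr5")
  out <- filter_genes(em, ann)
  expect_true("Gmystery" %in% out$matrix$gene_ids)
  expect_false(out$report$annotated[out$report$gene_id == "Gmystery"])
})

test_that("all genes removed is a hard error", {
  em <- expression_matrix(matrix(0, 4, 2), gene_ids = c("A", "B"))
  expect_error(filter_genes(em), "all genes removed")
})

test_that("imputation fills missing cells with the per-gene mean only", {
  v <- matrix(c(2, NA, 4,
                5, 5, NA), 3, 2)
  em <- expression_matrix(v, gene_ids = c("g1", "g2"))
  out <- impute_missing(em)
  expect_equal(out$values[, "g1"], c(2, 3, 4), ignore_attr = TRUE)
  expect_equal(out$values[3, "g2"], 5)          # constant-gene mean
  expect_equal(out$values[1:2, "g2"], c(5, 5), ignore_attr = TRUE)
  # a complete matrix passes through unchanged
  complete <- expression_matrix(matrix(runif(12), 4, 3))
  expect_identical(impute_missing(complete)$values, complete$values)
})

test_that("min-max normalization and its stored record", {
  em <- expression_matrix(matrix(c(2, 4, 6, 7, 7, 7), 3, 2),
                          gene_ids = c("g", "const"))
  out <- normalize_unit_interval(em)
  expect_equal(out$values[, "g"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(out$values[, "const"], c(0, 0, 0), ignore_attr = TRUE)
  # the record reproduces the normalized training matrix
  again <- apply_normalization(em, norm_record(out))
  expect_equal(again$values, out$values)
  # missing values refuse to normalize
  miss <- expression_matrix(matrix(c(1, NA), 2, 1))
  expect_error(normalize_unit_interval(miss), "missing")
})

test_that("filter-impute-normalize yields complete [0,1] matrices on random inputs", {
  for (i in 1:100) {
    set.seed(i)
    n <- sample(5:12, 1); g <- sample(6:15, 1)
    v <- matrix(rexp(n * g), n, g)
    v[sample(length(v), round(0.05 * length(v)))] <- NA
    ids <- sprintf("g%02d", seq_len(g))
    chroms <- sample(c("chr1", "chr2", "chrY"), g, replace = TRUE)
    zero_gene <- sample(g, 1)
    v[, zero_gene] <- 0
    em <- expression_matrix(v, gene_ids = ids)
    ann <- gene_annotation(ids, chroms)
    out <- tryCatch(preprocess_expression(em, ann),
                    error = function(e) NULL)
    if (is.null(out)) next   # everything filtered away: legitimately an error
    expect_false(anyNA(out$matrix$values))
    expect_true(all(out$matrix$values >= 0 & out$matrix$values <= 1))
    kept <- out$filter_report$status == "retained"
    expect_false(any(chroms[kept] == "chrY"))
    expect_false(ids[zero_gene] %in% out$matrix$gene_ids)
    expect_true(all(out$filter_report$na_fraction[kept] <= 0.1))
    # statuses partition the original gene count
    expect_equal(nrow(out$filter_report), g)
  }
})

test_that("expression round trip through TSV is lossless in ids and values", {
  ds <- small_dataset()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression(ds$matrix, path)
  back <- read_expression(path)
  expect_equal(back$gene_ids, ds$matrix$gene_ids)
  expect_equal(back$values, ds$matrix$values, tolerance = 1e-12)
})

test_that("gene-set files round trip one id per line", {
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_set(c("TP53", "BRCA1"), path)
  expect_equal(read_gene_set(path), c("TP53", "BRCA1"))
})
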