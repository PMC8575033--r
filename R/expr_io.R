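# Expression-matrix container, delimited-text IO, and the preprocessing chain
# (chrY / all-zero / high-NA gene filters, per-gene mean imputation, per-gene
# min-max normalization to [0,1]).

#' Expression matrix container
#'
#' Samples in rows, genes in columns. Values are non-negative expression
#' levels (FPKM-like units before normalization), `NA` for missing entries.
#'
#' @param values Numeric matrix, `n_samples x n_genes`.
#' @param gene_ids Unique gene identifiers (default: column names).
#' @param sample_ids Unique sample identifiers (default: row names).
#' @param class_labels Optional per-sample class labels (factor or character).
#' @param phenotypes Optional data frame of per-sample categorical covariates
#'   (e.g. sex), one row per sample.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, gene_ids = colnames(values),
                              sample_ids = rownames(values),
                              class_labels = NULL, phenotypes = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("G", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != ncol(values)) {
    stop("length(gene_ids) (", length(gene_ids), ") != number of gene columns (",
         ncol(values), ")")
  }
  if (length(sample_ids) != nrow(values)) {
    stop("length(sample_ids) (", length(sample_ids), ") != number of sample rows (",
         nrow(values), ")")
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene id(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicate sample id(s): ", paste(dup, collapse = ", "))
  bad <- which(!is.na(values) & (!is.finite(values) | values < 0), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("negative or non-finite expression value at sample '",
         sample_ids[bad[1L, 1L]], "', gene '", gene_ids[bad[1L, 2L]], "'")
  }
  if (!is.null(class_labels)) {
    if (length(class_labels) != nrow(values)) stop("class_labels length mismatch")
    class_labels <- factor(class_labels)
  }
  if (!is.null(phenotypes)) {
    phenotypes <- as.data.frame(phenotypes)
    if (nrow(phenotypes) != nrow(values)) stop("phenotypes row count mismatch")
  }
  dimnames(values) <- list(sample_ids, gene_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 class_labels = class_labels, phenotypes = phenotypes),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix> ", length(x$sample_ids), " samples x ",
      length(x$gene_ids), " genes; ", sum(is.na(x$values)), " missing value(s)",
      if (!is.null(x$class_labels))
        paste0("; ", nlevels(x$class_labels), " classes"), "\n", sep = "")
  invisible(x)
}

#' Number of genes / samples in an expression matrix
#' @param m An `expression_matrix`.
#' @return Integer count.
#' @export
n_genes <- function(m) length(m$gene_ids)

#' @rdname n_genes
#' @export
n_samples <- function(m) length(m$sample_ids)

.delim_for <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from delimited text
#'
#' The first column holds row identifiers; the header holds column identifiers.
#' Empty cells, `NA` and `N/A` parse as missing. Negative values, duplicate
#' identifiers and ragged rows are hard errors.
#'
#' @param path TSV or CSV file.
#' @param orientation `"genes_in_columns"` (rows are samples) or
#'   `"genes_in_rows"` (rows are genes; the matrix is transposed on read).
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return An `expression_matrix` with IDs preserved in file order.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_columns", "genes_in_rows"),
                            sep = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path, sep),
                          check.names = FALSE, na.strings = c("", "NA", "N/A"),
                          colClasses = NA, fill = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  row_ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  col_ids <- colnames(df)[-1L]
  dup <- unique(row_ids[duplicated(row_ids)])
  if (length(dup)) stop("duplicate row id(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  dup <- unique(col_ids[duplicated(col_ids)])
  if (length(dup)) stop("duplicate column id(s) in ", path, ": ",
                        paste(dup, collapse = ", "))
  if (orientation == "genes_in_rows") {
    vals <- t(vals)
    expression_matrix(vals, gene_ids = row_ids, sample_ids = col_ids)
  } else {
    expression_matrix(vals, gene_ids = col_ids, sample_ids = row_ids)
  }
}

#' Write an expression matrix as TSV (samples in rows)
#'
#' @param m An `expression_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(sample_id = m$sample_ids, m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene annotation table
#'
#' Maps gene id to chromosome label; `"chrY"` is recognised by the gene filter.
#' Genes absent from the annotation are permitted (they are retained and
#' flagged by [filter_genes()]).
#'
#' @param gene_id Character vector of gene ids.
#' @param chromosome Character vector of chromosome labels, same length.
#' @return A `gene_annotation` data frame.
#' @export
gene_annotation <- function(gene_id, chromosome) {
  gene_id <- as.character(gene_id)
  chromosome <- as.character(chromosome)
  if (length(gene_id) != length(chromosome)) stop("length mismatch")
  dup <- unique(gene_id[duplicated(gene_id)])
  if (length(dup)) stop("duplicate annotated gene id(s): ",
                        paste(dup, collapse = ", "))
  structure(data.frame(gene_id = gene_id, chromosome = chromosome,
                       stringsAsFactors = FALSE),
            class = c("gene_annotation", "data.frame"))
}

#' Read a two-column gene annotation TSV (gene_id, chromosome)
#' @param path TSV file with a header row.
#' @return A `gene_annotation`.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  gene_annotation(df[[1L]], df[[2L]])
}

#' Filter genes by chromosome, expression and missingness
#'
#' Removes, in reporting order: (a) genes annotated to chrY, (b) genes whose
#' non-missing values are all zero, (c) genes missing in strictly more than
#' `na_fraction_max` of samples. A gene matching several rules is reported
#' under the first. Genes without annotation are kept and flagged.
#'
#' @param m An `expression_matrix`.
#' @param annotation Optional [gene_annotation()].
#' @param na_fraction_max Maximum tolerated missing fraction (default 0.1;
#'   a gene missing in exactly this fraction is retained).
#' @return List with `matrix` (the surviving genes, order preserved) and
#'   `report`, a data frame with one row per original gene: `gene_id`,
#'   `status` (`retained`/`removed_chrY`/`removed_all_zero`/`removed_na`),
#'   `na_fraction`, `annotated`.
#' @export
filter_genes <- function(m, annotation = NULL, na_fraction_max = 0.1) {
  stopifnot(inherits(m, "expression_matrix"))
  if (na_fraction_max < 0 || na_fraction_max > 1) {
    stop("na_fraction_max must be in [0, 1]")
  }
  v <- m$values
  chrom <- rep(NA_character_, n_genes(m))
  if (!is.null(annotation)) {
    chrom <- annotation$chromosome[match(m$gene_ids, annotation$gene_id)]
  }
  annotated <- !is.na(chrom)
  is_y <- annotated & chrom == "chrY"
  na_frac <- colMeans(is.na(v))
  nonmiss <- colSums(!is.na(v))
  all_zero <- nonmiss > 0 & colSums(v != 0, na.rm = TRUE) == 0
  high_na <- na_frac > na_fraction_max
  # precedence for reporting: chrY first, then all-zero, then NA
  status <- rep("retained", n_genes(m))
  status[high_na] <- "removed_na"
  status[all_zero] <- "removed_all_zero"
  status[is_y] <- "removed_chrY"
  report <- data.frame(gene_id = m$gene_ids, status = status,
                       na_fraction = na_frac, annotated = annotated,
                       stringsAsFactors = FALSE)
  keep <- status == "retained"
  if (!any(keep)) stop("all genes removed by filtering")
  kept <- expression_matrix(v[, keep, drop = FALSE],
                            gene_ids = m$gene_ids[keep],
                            sample_ids = m$sample_ids,
                            class_labels = m$class_labels,
                            phenotypes = m$phenotypes)
  list(matrix = kept, report = report)
}

#' Impute missing values by the per-gene mean
#'
#' Each missing cell is replaced by the mean of that gene's observed values;
#' observed cells are untouched.
#'
#' @param m An `expression_matrix` in which every gene has at least one
#'   observed value.
#' @return A complete `expression_matrix`.
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  v <- m$values
  if (!anyNA(v)) return(m)
  nonmiss <- colSums(!is.na(v))
  if (any(nonmiss == 0)) {
    stop("gene(s) with no observed values (should have been filtered): ",
         paste(utils::head(m$gene_ids[nonmiss == 0], 5L), collapse = ", "))
  }
  mu <- colMeans(v, na.rm = TRUE)
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- mu[idx[, 2L]]
  m$values <- v
  m
}

#' Normalize each gene to the unit interval
#'
#' Per gene, `v <- (v - min) / (max - min)` over the given matrix; constant
#' genes map to 0 everywhere. The returned object carries a per-gene
#' `(min, max)` record (see [norm_record()]) sufficient to normalize new
#' samples identically via [apply_normalization()].
#'
#' @param m A complete `expression_matrix` (no missing values).
#' @return The normalized `expression_matrix` with a `norm_record` attribute.
#' @export
normalize_unit_interval <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (anyNA(m$values)) stop("missing values present; impute before normalizing")
  mins <- apply(m$values, 2L, min)
  maxs <- apply(m$values, 2L, max)
  rec <- data.frame(gene_id = m$gene_ids, min = mins, max = maxs,
                    row.names = NULL, stringsAsFactors = FALSE)
  m <- apply_normalization(m, rec)
  attr(m, "norm_record") <- rec
  m
}

#' Per-gene normalization record of a normalized matrix
#' @param m A matrix returned by [normalize_unit_interval()].
#' @return Data frame with columns `gene_id`, `min`, `max`.
#' @export
norm_record <- function(m) attr(m, "norm_record")

#' Apply a stored per-gene (min, max) record to new samples
#'
#' @param m An `expression_matrix` whose genes appear in `record`.
#' @param record Data frame from [norm_record()] (or the JSON sidecar).
#' @return The normalized `expression_matrix`.
#' @export
apply_normalization <- function(m, record) {
  stopifnot(inherits(m, "expression_matrix"))
  i <- match(m$gene_ids, record$gene_id)
  if (anyNA(i)) {
    stop("genes missing from normalization record: ",
         paste(utils::head(m$gene_ids[is.na(i)], 5L), collapse = ", "))
  }
  mins <- record$min[i]
  rng <- record$max[i] - mins
  v <- sweep(m$values, 2L, mins, "-")
  scale <- ifelse(rng > 0, rng, 1)     # constant genes -> 0 everywhere
  v <- sweep(v, 2L, scale, "/")
  v[, rng == 0] <- 0
  m$values <- v
  m
}

#' Full preprocessing chain: filter, impute, normalize
#'
#' @inheritParams filter_genes
#' @return List with `matrix` (complete, in `[0,1]`), `filter_report` and
#'   `norm_record`.
#' @export
preprocess_expression <- function(m, annotation = NULL, na_fraction_max = 0.1) {
  flt <- filter_genes(m, annotation, na_fraction_max)
  out <- normalize_unit_interval(impute_missing(flt$matrix))
  list(matrix = out, filter_report = flt$report, norm_record = norm_record(out))
}

#' Read / write a gene-set file (one gene id per line)
#' @param path Text file.
#' @return Character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  ids[nzchar(ids)]
}

#' @rdname read_gene_set
#' @param ids Character vector of gene ids to write.
#' @export
write_gene_set <- function(ids, path) {
  writeLines(as.character(ids), path)
  invisible(path)
}

#' Write / read a ranked feature table (rank, gene_id, score)
#' @param ranked A ranked list from [aggregate_abs_mean()] or kin.
#' @param path TSV file.
#' @export
write_ranked_genes <- function(ranked, path) {
  utils::write.table(as.data.frame(ranked)[, c("rank", "gene_id", "score")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_genes
#' @export
read_ranked_genes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  structure(df, class = c("ranked_gene_list", "data.frame"))
}
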