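# Planted-signal synthetic expression data. Emulates the shape of a
# pan-cancer bulk expression matrix after [0,1] normalization: many more
# genes than samples, a small disjoint set of discriminative genes per class,
# and a binary sex-analogue covariate driven by one designated gene (the
# XIST-like driver), so attribution and latent-space results are checkable
# against known ground truth.

#' Specification for a synthetic planted-signal dataset
#'
#' Defaults are the package's standard study fixture: 600 samples, 2000 genes,
#' 4 balanced classes with 25 planted genes each, a +0.4 mean shift on planted
#' genes (normalized units) over Gaussian background noise of sd 0.1, 2%
#' missing cells, and the last gene as the sex driver.
#'
#' @param n_samples,n_genes Matrix dimensions.
#' @param n_classes Number of classes (>= 2), balanced.
#' @param planted_per_class Planted discriminative genes per class; planted
#'   sets are disjoint across classes.
#' @param effect_size Mean shift added to a class's planted genes in that
#'   class's samples (normalized units, > 0; values are clipped to 1).
#' @param noise_sd Background Gaussian noise sd around 0.5.
#' @param na_rate Fraction of cells masked missing uniformly at random.
#' @param sex_gene_index Index of the gene encoding the binary sex covariate
#'   (near 1 for one sex, near 0 for the other), or `NULL` for none.
#'   Defaults to the last gene.
#' @param seed Integer seed; the dataset is fully determined by it.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_samples = 600L, n_genes = 2000L, n_classes = 4L,
                           planted_per_class = 25L, effect_size = 0.4,
                           noise_sd = 0.1, na_rate = 0.02,
                           sex_gene_index = n_genes, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               n_classes = as.integer(n_classes),
               planted_per_class = as.integer(planted_per_class),
               effect_size = effect_size, noise_sd = noise_sd,
               na_rate = na_rate,
               sex_gene_index = if (is.null(sex_gene_index)) NULL
                                else as.integer(sex_gene_index),
               seed = as.integer(seed))
  if (spec$n_classes < 2L) stop("n_classes must be >= 2")
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  if (spec$na_rate < 0 || spec$na_rate > 1) stop("na_rate must be in [0, 1]")
  if (spec$planted_per_class * spec$n_classes > spec$n_genes) {
    stop("planted_per_class * n_classes (",
         spec$planted_per_class * spec$n_classes,
         ") exceeds n_genes (", spec$n_genes, ")")
  }
  if (!is.null(spec$sex_gene_index) &&
      (spec$sex_gene_index < 1L || spec$sex_gene_index > spec$n_genes)) {
    stop("sex_gene_index out of range")
  }
  structure(spec, class = "synthetic_spec")
}

#' Generate a planted-signal expression dataset
#'
#' Background values are Gaussian noise around 0.5 clipped to `[0,1]`; each
#' class's planted genes are shifted by `+effect_size` (clipped at 1) in that
#' class's samples; the sex gene sits near 1 for females and near 0 for males;
#' `na_rate` of cells are masked missing. Fully determined by `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `matrix` (an [expression_matrix()] carrying class labels
#'   and a `sex` phenotype) and `truth`, a `ground_truth` object with the
#'   planted gene index sets, labels and the sex gene index.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_samples; g <- spec$n_genes
    classes <- paste0("C", seq_len(spec$n_classes))
    labels <- factor(classes[1L + (seq_len(n) - 1L) %% spec$n_classes],
                     levels = classes)
    labels <- labels[sample.int(n)]
    sex <- sample(c("female", "male"), n, replace = TRUE)

    pool <- seq_len(g)
    if (!is.null(spec$sex_gene_index)) pool <- setdiff(pool, spec$sex_gene_index)
    picked <- sample(pool, spec$planted_per_class * spec$n_classes)
    planted <- split(picked, rep(seq_len(spec$n_classes),
                                 each = spec$planted_per_class))
    names(planted) <- classes

    v <- matrix(stats::rnorm(n * g, mean = 0.5, sd = spec$noise_sd), n, g)
    for (c in seq_len(spec$n_classes)) {
      rows <- which(labels == classes[c])
      v[rows, planted[[c]]] <- v[rows, planted[[c]]] + spec$effect_size
    }
    if (!is.null(spec$sex_gene_index)) {
      j <- spec$sex_gene_index
      v[, j] <- stats::rnorm(n, mean = ifelse(sex == "female", 0.95, 0.05),
                             sd = 0.02)
    }
    v <- pmin(pmax(v, 0), 1)
    if (spec$na_rate > 0) {
      v[matrix(stats::runif(n * g) < spec$na_rate, n, g)] <- NA_real_
    }

    gene_ids <- sprintf("G%04d", seq_len(g))
    sample_ids <- sprintf("S%04d", seq_len(n))
    em <- expression_matrix(v, gene_ids = gene_ids, sample_ids = sample_ids,
                            class_labels = labels,
                            phenotypes = data.frame(sex = sex,
                                                    stringsAsFactors = FALSE))
    truth <- structure(list(planted = planted,
                            class_labels = as.character(labels),
                            sex_labels = sex,
                            sex_gene_index = spec$sex_gene_index,
                            spec = unclass(spec)),
                       class = "ground_truth")
    validate_ground_truth(truth)
    list(matrix = em, truth = truth)
  })
}

#' Validate a ground-truth object
#'
#' Checks the invariants of a planted-signal ground truth: disjoint planted
#' sets, in-range indices, consistent label lengths.
#'
#' @param truth A `ground_truth` object.
#' @return `truth`, invisibly; errors if invalid.
#' @export
validate_ground_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  all_planted <- unlist(truth$planted, use.names = FALSE)
  if (anyDuplicated(all_planted)) {
    stop("planted gene sets overlap across classes")
  }
  g <- truth$spec$n_genes
  if (any(all_planted < 1L | all_planted > g)) stop("planted index out of range")
  if (length(truth$class_labels) != truth$spec$n_samples ||
      length(truth$sex_labels) != truth$spec$n_samples) {
    stop("label length inconsistent with spec")
  }
  if (!is.null(truth$sex_gene_index) && truth$sex_gene_index %in% all_planted) {
    stop("sex gene collides with a planted set")
  }
  invisible(truth)
}

#' Planted gene ids for one class
#' @param truth A `ground_truth`.
#' @param class_label Class name (e.g. `"C1"`).
#' @param gene_ids Gene id vector of the matrix the truth refers to.
#' @return Character vector of planted gene ids.
#' @export
planted_gene_ids <- function(truth, class_label, gene_ids) {
  idx <- truth$planted[[class_label]]
  if (is.null(idx)) stop("unknown class label: ", class_label)
  gene_ids[idx]
}

#' Write / read a synthetic fixture directory
#'
#' Layout: `matrix.tsv` (samples x genes), `labels.tsv`, `phenotypes.tsv`,
#' `truth.json`. The round trip is lossless up to text float precision, and
#' reading re-validates the ground-truth invariants.
#'
#' @param dataset List from [generate_dataset()].
#' @param dir Directory (created if needed).
#' @return `dir` (write) or the dataset list (read).
#' @export
write_fixture <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(dataset$matrix, file.path(dir, "matrix.tsv"))
  utils::write.table(
    data.frame(sample_id = dataset$matrix$sample_ids,
               class = as.character(dataset$matrix$class_labels)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    cbind(data.frame(sample_id = dataset$matrix$sample_ids),
          dataset$matrix$phenotypes),
    file.path(dir, "phenotypes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  jsonlite::write_json(unclass(dataset$truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_fixture
#' @export
read_fixture <- function(dir) {
  paths <- file.path(dir, c("matrix.tsv", "labels.tsv", "phenotypes.tsv",
                            "truth.json"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("fixture file(s) missing: ",
                            paste(basename(missing), collapse = ", "))
  em <- read_expression(paths[1L], orientation = "genes_in_columns")
  labels <- utils::read.table(paths[2L], header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  pheno <- utils::read.table(paths[3L], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  stopifnot(identical(labels$sample_id, em$sample_ids),
            identical(pheno$sample_id, em$sample_ids))
  tr <- jsonlite::read_json(paths[4L], simplifyVector = TRUE)
  truth <- structure(list(planted = lapply(tr$planted, as.integer),
                          class_labels = as.character(tr$class_labels),
                          sex_labels = as.character(tr$sex_labels),
                          sex_gene_index = if (is.null(tr$sex_gene_index)) NULL
                                           else as.integer(tr$sex_gene_index),
                          spec = tr$spec),
                     class = "ground_truth")
  validate_ground_truth(truth)
  em <- expression_matrix(em$values, em$gene_ids, em$sample_ids,
                          class_labels = labels$class,
                          phenotypes = pheno[, -1L, drop = FALSE])
  list(matrix = em, truth = truth)
}
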