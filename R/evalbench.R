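# Validation machinery for ranked gene lists: ROC against a curated gene set
# over gene-count thresholds, method comparison on planted-truth fixtures,
# top-k retraining, overall rank-sum importance, and gene-list overlap.

#' ROC of a ranked gene list against a curated gene set
#'
#' At each gene-count cutoff k (thresholds evenly spaced over 1..n_genes,
#' both endpoints included), TPR is the fraction of the truth set among the
#' top k and FPR the fraction of non-truth genes among the top k. AUC is the
#' trapezoid over (FPR, TPR) with the (0,0) endpoint prepended.
#'
#' @param ranked A `ranked_gene_list` (descending importance).
#' @param truth_set Character vector of gene ids; must be a non-empty proper
#'   subset of the ranked universe.
#' @param n_thresholds Number of cutoffs (default 100).
#' @return An `eval_curve`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_against_gene_set <- function(ranked, truth_set, n_thresholds = 100L) {
  ids <- ranked$gene_id
  n <- length(ids)
  truth_set <- unique(as.character(truth_set))
  if (!length(truth_set)) stop("truth set is empty")
  if (!all(truth_set %in% ids)) {
    stop("truth set contains genes outside the ranked universe: ",
         paste(utils::head(setdiff(truth_set, ids), 5L), collapse = ", "))
  }
  if (length(truth_set) >= n) stop("truth set covers the whole gene universe")
  ks <- unique(round(seq(1L, n, length.out = min(n_thresholds, n))))
  ks <- sort(unique(c(1L, ks, n)))
  is_truth <- ids %in% truth_set
  cum_tp <- cumsum(is_truth)
  tpr <- cum_tp[ks] / length(truth_set)
  fpr <- (ks - cum_tp[ks]) / (n - length(truth_set))
  fpr_full <- c(0, fpr); tpr_full <- c(0, tpr)
  auc <- sum(diff(fpr_full) * (utils::head(tpr_full, -1L) +
                                 utils::tail(tpr_full, -1L)) / 2)
  structure(list(thresholds = ks, tpr = tpr, fpr = fpr, auc = auc),
            class = "eval_curve")
}

#' @export
print.eval_curve <- function(x, ...) {
  cat("<eval_curve> ", length(x$thresholds), " thresholds, AUC = ",
      format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

.random_ranking <- function(ids, seed) {
  withr::with_seed(seed, ord <- sample(ids))
  .ranked_from_scores(stats::setNames(rev(seq_along(ord)), ord)[ids], ids,
                      provenance = list(method = "random", seed = seed))
}

#' Compare attribution methods by planted-gene ROC AUC
#'
#' For every class of a planted-truth fixture and every method, ranks the
#' genes for that class and scores the ranking against the class's planted
#' set; AUCs are averaged over classes and seeds (seeds drive the reference
#' draw, the gradient-shap sampling and the random-ranking arm).
#'
#' @param model A trained `vae_classifier`.
#' @param dataset A list with `matrix` and `truth` from [generate_dataset()].
#' @param methods Character subset of `c("rescale", "saliency",
#'   "input_x_gradient", "gradient_shap", "random")`.
#' @param k_refs References per draw (default 50).
#' @param seeds Integer vector of seeds (default 1:3).
#' @return Data frame: `method`, `mean_auc`, `sd_auc`.
#' @export
compare_methods <- function(model, dataset,
                            methods = c("rescale", "saliency",
                                        "input_x_gradient", "gradient_shap",
                                        "random"),
                            k_refs = 50L, seeds = 1:3) {
  methods <- match.arg(methods, several.ok = TRUE)
  em <- dataset$matrix; truth <- dataset$truth
  classes <- levels(em$class_labels)
  aucs <- sapply(methods, function(me) {
    vapply(seeds, function(sd) {
      refs <- build_reference_set(em, "random_train", k_refs = k_refs,
                                  seed = sd)
      mean(vapply(classes, function(cl) {
        truth_ids <- planted_gene_ids(truth, cl, em$gene_ids)
        rows <- which(em$class_labels == cl)
        samples <- em$values[rows, , drop = FALSE]
        ranked <- if (me == "rescale") {
          explain_class_by_genes(model, cl, samples, refs)
        } else if (me == "random") {
          .random_ranking(em$gene_ids, seed = sd * 1000L + match(cl, classes))
        } else {
          aggregate_abs_mean(baseline_attribution(
            me, model, samples, refs,
            target_spec("class_logit", cl, "input_genes"), seed = sd))
        }
        roc_against_gene_set(ranked, truth_ids)$auc
      }, numeric(1)))
    }, numeric(1))
  })
  aucs <- matrix(aucs, nrow = length(seeds),
                 dimnames = list(NULL, methods))
  data.frame(method = methods,
             mean_auc = colMeans(aucs),
             sd_auc = apply(aucs, 2L, stats::sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

.binary_metrics <- function(truth_pos, pred_pos, score) {
  tp <- sum(truth_pos & pred_pos); fp <- sum(!truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  ppv <- if (tp + fp == 0) 0 else tp / (tp + fp)
  tpr <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (ppv + tpr == 0) 0 else 2 * ppv * tpr / (ppv + tpr)
  # rank-statistic AUC of the class score
  r <- rank(score)
  n1 <- sum(truth_pos); n0 <- sum(!truth_pos)
  auc <- if (n1 == 0 || n0 == 0) NA_real_
         else (sum(r[truth_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(F1 = f1, PPV = ppv, TPR = tpr, AUC = auc)
}

.one_vs_rest_metrics <- function(model, m_test, target_class) {
  pr <- predict(model, m_test)
  truth <- as.character(m_test$class_labels)
  other <- setdiff(levels(m_test$class_labels), target_class)
  tgt <- .binary_metrics(truth == target_class,
                         as.character(pr$class) == target_class,
                         pr$probabilities[, target_class])
  oth <- rowMeans(vapply(other, function(cl) {
    .binary_metrics(truth == cl, as.character(pr$class) == cl,
                    pr$probabilities[, cl])
  }, numeric(4)))
  list(target = tgt, others = oth)
}

.subset_genes <- function(m, gene_ids) {
  expression_matrix(m$values[, gene_ids, drop = FALSE], gene_ids = gene_ids,
                    sample_ids = m$sample_ids, class_labels = m$class_labels,
                    phenotypes = m$phenotypes)
}

#' Retrain on the top-k ranked genes versus k random genes
#'
#' Trains a fresh model on only the top-k gene columns of the ranking, and,
#' separately, on k uniformly random genes per seed, with the parent
#' hyperparameters except the input width. Reports one-vs-rest F1, PPV, TPR
#' and AUC for the target class and the macro average over the other classes,
#' on a held-out stratified split.
#'
#' @param m A labelled, preprocessed [expression_matrix()].
#' @param ranked A `ranked_gene_list` over `m`'s genes.
#' @param k Number of genes (default 20).
#' @param n_random_seeds Random-gene repetitions (default 10).
#' @param target_class The class of interest.
#' @param hyper [vae_hyperparams()] for the retrained models.
#' @param test_fraction Held-out fraction (default 0.2).
#' @return A `retrain_report` data frame: one row per metric with columns
#'   `target_top`, `target_random_mean`, `target_random_sd`, `others_top`,
#'   `others_random_mean`, `others_random_sd`; the per-seed random-arm values
#'   are kept in the `random_arm` attribute.
#' @export
retrain_top_k <- function(m, ranked, k = 20L, n_random_seeds = 10L,
                          target_class, hyper = vae_hyperparams(),
                          test_fraction = 0.2) {
  if (k >= n_genes(m)) stop("k must be smaller than the gene universe")
  if (!target_class %in% levels(m$class_labels)) {
    stop("class '", target_class, "' absent from the labels")
  }
  split <- stratified_split(m$class_labels, test_fraction, seed = hyper$seed)
  fit_eval <- function(gene_ids, seed) {
    h <- hyper; h$seed <- as.integer(seed)
    sub <- .subset_genes(m, gene_ids)
    tr <- expression_matrix(sub$values[split$train, , drop = FALSE],
                            gene_ids = sub$gene_ids,
                            sample_ids = sub$sample_ids[split$train],
                            class_labels = sub$class_labels[split$train])
    te <- expression_matrix(sub$values[split$test, , drop = FALSE],
                            gene_ids = sub$gene_ids,
                            sample_ids = sub$sample_ids[split$test],
                            class_labels = sub$class_labels[split$test])
    .one_vs_rest_metrics(train_vae_classifier(tr, h), te, target_class)
  }
  top <- fit_eval(ranked$gene_id[seq_len(k)], hyper$seed + 1L)
  rand <- lapply(seq_len(n_random_seeds), function(s) {
    withr::with_seed(hyper$seed + 100L + s,
                     ids <- sample(m$gene_ids, k))
    fit_eval(ids, hyper$seed + 100L + s)
  })
  rt <- t(vapply(rand, `[[`, numeric(4), "target"))
  ro <- t(vapply(rand, `[[`, numeric(4), "others"))
  out <- data.frame(metric = names(top$target),
                    target_top = unname(top$target),
                    target_random_mean = colMeans(rt),
                    target_random_sd = apply(rt, 2L, stats::sd),
                    others_top = unname(top$others),
                    others_random_mean = colMeans(ro),
                    others_random_sd = apply(ro, 2L, stats::sd),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "random_arm") <- list(target = rt, others = ro,
                                  n_seeds = n_random_seeds)
  structure(out, class = c("retrain_report", "data.frame"))
}

#' Overall gene importance by summed per-class ranks
#'
#' Sums each gene's rank across the per-class rankings (rank 1 = most
#' important). The output is ordered by ascending rank-sum, so the head holds
#' the overall most important genes and the tail the least important; ties
#' break on gene id.
#'
#' @param per_class_rankings List of `ranked_gene_list`s over one common gene
#'   universe.
#' @return A `ranked_gene_list` whose `score` is the rank-sum (ascending).
#' @export
rank_sum_overall <- function(per_class_rankings) {
  stopifnot(length(per_class_rankings) >= 1L)
  universe <- sort(per_class_rankings[[1L]]$gene_id)
  for (r in per_class_rankings[-1L]) {
    if (!identical(sort(r$gene_id), universe)) {
      d <- union(setdiff(r$gene_id, universe), setdiff(universe, r$gene_id))
      stop("rankings cover different gene universes; symmetric difference: ",
           paste(utils::head(d, 5L), collapse = ", "))
    }
  }
  sums <- rowSums(vapply(per_class_rankings, function(r) {
    r$rank[match(universe, r$gene_id)]
  }, numeric(length(universe))))
  .ranked_from_scores(sums, universe,
                      provenance = list(n_rankings = length(per_class_rankings)),
                      direction = "ascending")
}

#' Bottom-k accessor of an ascending rank-sum list
#' @param ranked Result of [rank_sum_overall()].
#' @param k How many least-important genes.
#' @return Character vector of gene ids.
#' @export
bottom_k_genes <- function(ranked, k) {
  utils::tail(ranked$gene_id, k)
}

#' Overlap between two gene lists
#'
#' @param list_a,list_b Character vectors of gene ids (e.g. a top-k list and
#'   an externally derived DEG list).
#' @return List with `intersection` (count) and `jaccard`.
#' @export
overlap_count <- function(list_a, list_b) {
  a <- unique(as.character(list_a)); b <- unique(as.character(list_b))
  i <- length(intersect(a, b))
  u <- length(union(a, b))
  list(intersection = i, jaccard = if (u == 0) 0 else i / u)
}
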