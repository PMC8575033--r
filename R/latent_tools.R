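# Unsupervised cluster explanation over the latent space: Welch's t-test on
# the per-sample latent means between two groups, and the sign-flip ablation
# protocol measuring how much each latent dimension is needed for
# classification.

#' Rank latent dimensions by Welch's t-test between two groups
#'
#' Per dimension, the unequal-variance two-sample t statistic
#' `t = (m_A - m_B) / sqrt(s_A^2/n_A + s_B^2/n_B)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value. Dimensions are ranked by p
#' ascending, ties by `|t|` descending then dimension index. A dimension with
#' zero pooled standard error is degenerate: it gets `t = 0`, `p = 1` and a
#' flag.
#'
#' @param mu_a,mu_b Latent mean matrices (samples x latent_dim) of the two
#'   groups, e.g. from [encode()]; both need at least 2 rows.
#' @return A `latent_group_stats` data frame, one row per dimension, ordered
#'   by rank: `dimension`, `mean_a`, `sd_a`, `n_a`, `mean_b`, `sd_b`, `n_b`,
#'   `t_statistic`, `welch_df`, `p_value`, `degenerate`, `rank`.
#' @export
welch_rank_dimensions <- function(mu_a, mu_b) {
  mu_a <- as.matrix(mu_a); mu_b <- as.matrix(mu_b)
  if (ncol(mu_a) != ncol(mu_b)) stop("groups have different latent widths")
  n_a <- nrow(mu_a); n_b <- nrow(mu_b)
  if (n_a < 2L || n_b < 2L) stop("both groups need at least 2 samples")
  m_a <- colMeans(mu_a); m_b <- colMeans(mu_b)
  v_a <- colSums(sweep(mu_a, 2L, m_a)^2) / (n_a - 1L)
  v_b <- colSums(sweep(mu_b, 2L, m_b)^2) / (n_b - 1L)
  se2 <- v_a / n_a + v_b / n_b
  degenerate <- se2 == 0
  t_stat <- ifelse(degenerate, 0, (m_a - m_b) / sqrt(se2))
  df <- ifelse(degenerate, NA_real_,
               se2^2 / ((v_a / n_a)^2 / (n_a - 1L) + (v_b / n_b)^2 / (n_b - 1L)))
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t_stat), df))
  p <- pmax(p, .Machine$double.xmin)   # keep p in (0, 1]
  d <- seq_len(ncol(mu_a))
  out <- data.frame(dimension = d, mean_a = m_a, sd_a = sqrt(v_a), n_a = n_a,
                    mean_b = m_b, sd_b = sqrt(v_b), n_b = n_b,
                    t_statistic = t_stat, welch_df = df, p_value = p,
                    degenerate = degenerate, row.names = NULL)
  out <- out[order(out$p_value, -abs(out$t_statistic), out$dimension), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("latent_group_stats", "data.frame"))
}

#' Welch ranking between two labelled sample groups
#'
#' Convenience wrapper: encodes the two groups with the model and runs
#' [welch_rank_dimensions()] on their latent means.
#'
#' @param model A `vae_classifier`.
#' @param m An [expression_matrix()].
#' @param group_a,group_b Logical vectors over samples, or values matched
#'   against the class labels.
#' @return A `latent_group_stats`.
#' @export
compare_latent_groups <- function(model, m, group_a, group_b) {
  pick <- function(g) {
    if (is.logical(g)) which(g) else which(as.character(m$class_labels) %in% g)
  }
  ia <- pick(group_a); ib <- pick(group_b)
  mu <- encode(model, m)$mu
  welch_rank_dimensions(mu[ia, , drop = FALSE], mu[ib, , drop = FALSE])
}

#' Sign-flip ablation of latent dimensions
#'
#' Returns a copy of the model in which, at prediction time, each listed
#' latent mean is replaced by -1 when positive and by +1 when negative
#' (exact zeros are left unchanged), perturbing the dimension away from its
#' value. The original model is not modified, and re-applying the same spec
#' is idempotent.
#'
#' @param model A `vae_classifier`.
#' @param dims Integer latent dimension indices to ablate (may be empty).
#' @return The ablated model copy.
#' @export
ablate <- function(model, dims) {
  stopifnot(inherits(model, "vae_classifier"))
  dims <- as.integer(dims)
  if (length(dims) && (min(dims) < 1L || max(dims) > model$hyper$latent_dim)) {
    stop("ablation index out of range 1..", model$hyper$latent_dim)
  }
  model$ablated_dims <- sort(unique(c(model$ablated_dims, dims)))
  model
}

#' Accuracy impact of ablating ranked latent dimensions
#'
#' For each position set (by default: the 1st, 2nd and 3rd most important
#' dimensions individually, the top three combined, the three least important
#' individually, and the bottom three combined), reports the change in
#' overall accuracy and in per-class one-vs-rest recall when those dimensions
#' are sign-flip ablated, relative to the intact model.
#'
#' @param model A trained `vae_classifier`.
#' @param m A labelled [expression_matrix()] (typically the held-out split).
#' @param ranked_dims Dimensions in decreasing importance: an integer vector,
#'   or a ranking from [explain_class_by_latent()] /
#'   [welch_rank_dimensions()].
#' @param positions Named list of integer index vectors *into the ranking*
#'   (1 = most important); `NULL` for the default battery.
#' @return Data frame with one row per position set: `position`,
#'   `dimensions`, `accuracy`, `accuracy_change`, `mean_recall_change`,
#'   `sd_recall_change`.
#' @export
ablation_study <- function(model, m, ranked_dims, positions = NULL) {
  stopifnot(!is.null(m$class_labels), n_samples(m) > 0)
  if (inherits(ranked_dims, "latent_group_stats")) {
    ranked_dims <- ranked_dims$dimension
  } else if (inherits(ranked_dims, "ranked_gene_list")) {
    ranked_dims <- attr(ranked_dims, "dim_index") %||%
      as.integer(sub("dim_", "", ranked_dims$gene_id))
  }
  ranked_dims <- as.integer(ranked_dims)
  k <- length(ranked_dims)
  if (is.null(positions)) {
    positions <- list(`1st` = 1L, `2nd` = 2L, `3rd` = 3L, top3 = 1:3,
                      last3_1 = k - 2L, last3_2 = k - 1L, last3_3 = k,
                      bottom3 = (k - 2L):k)
  }
  truth <- as.character(m$class_labels)
  classes <- levels(m$class_labels)
  recall <- function(pred) {
    vapply(classes, function(cl) {
      idx <- truth == cl
      if (!any(idx)) NA_real_ else mean(pred[idx] == cl)
    }, numeric(1))
  }
  base_pred <- as.character(predict(model, m)$class)
  base_acc <- mean(base_pred == truth)
  base_rec <- recall(base_pred)
  rows <- lapply(names(positions), function(nm) {
    dims <- ranked_dims[positions[[nm]]]
    pred <- as.character(predict(ablate(model, dims), m)$class)
    rec_change <- recall(pred) - base_rec
    data.frame(position = nm,
               dimensions = paste(dims, collapse = ","),
               accuracy = mean(pred == truth),
               accuracy_change = mean(pred == truth) - base_acc,
               mean_recall_change = mean(rec_change, na.rm = TRUE),
               sd_recall_change = stats::sd(rec_change[!is.na(rec_change)]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_accuracy") <- base_acc
  out
}

#' Per-class ablation battery
#'
#' The per-tumour framing of the ablation protocol: for every class, that
#' class's own dimension ranking is ablated at each position set and the
#' change in the class's one-vs-rest recall is measured; position sets are
#' then summarised as mean and sd across classes. Defaults probe the 1st,
#' 2nd and 3rd most important dimensions individually, the top three
#' combined, the three least important individually, and the bottom three
#' combined.
#'
#' @param model A trained `vae_classifier`.
#' @param m A labelled [expression_matrix()] (typically the held-out split).
#' @param rankings Named list (one entry per class) of dimension orderings,
#'   each an integer vector or a ranking from [explain_class_by_latent()] /
#'   [welch_rank_dimensions()].
#' @param positions Named list of index vectors into each ranking
#'   (1 = most important); `NULL` for the default battery.
#' @return List with `per_class` (long data frame: class, position,
#'   recall_change) and `summary` (position, mean_change, sd_change).
#' @export
per_class_ablation_study <- function(model, m, rankings, positions = NULL) {
  stopifnot(!is.null(m$class_labels))
  classes <- names(rankings)
  if (is.null(classes) || !all(classes %in% levels(m$class_labels))) {
    stop("rankings must be a named list keyed by class label")
  }
  as_dims <- function(r) {
    if (inherits(r, "latent_group_stats")) r$dimension
    else if (inherits(r, "ranked_gene_list")) {
      attr(r, "dim_index") %||% as.integer(sub("dim_", "", r$gene_id))
    } else as.integer(r)
  }
  truth <- as.character(m$class_labels)
  pred_base <- as.character(predict(model, m)$class)
  rows <- list()
  for (cl in classes) {
    dims <- as_dims(rankings[[cl]])
    k <- length(dims)
    pos <- positions %||% list(`1st` = 1L, `2nd` = 2L, `3rd` = 3L, top3 = 1:3,
                               last3_1 = k - 2L, last3_2 = k - 1L, last3_3 = k,
                               bottom3 = (k - 2L):k)
    idx <- truth == cl
    base <- mean(pred_base[idx] == cl)
    for (nm in names(pos)) {
      pred <- as.character(predict(ablate(model, dims[pos[[nm]]]), m)$class)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, position = nm,
        recall_change = mean(pred[idx] == cl) - base,
        stringsAsFactors = FALSE)
    }
  }
  per_class <- do.call(rbind, rows)
  agg <- split(per_class$recall_change, per_class$position)
  pos_names <- unique(per_class$position)
  summary <- data.frame(position = pos_names,
                        mean_change = vapply(agg[pos_names], mean, numeric(1)),
                        sd_change = vapply(agg[pos_names], stats::sd, numeric(1)),
                        row.names = NULL, stringsAsFactors = FALSE)
  list(per_class = per_class, summary = summary)
}
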