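# Multi-level attribution over the trained model: gene -> class logit,
# latent dimension -> class logit, and gene -> latent dimension, all via
# rescale-rule difference-from-reference propagation with summation-to-delta,
# plus gradient-based baseline methods and absolute-mean aggregation into
# ranked feature lists.

#' Declare an attribution target
#'
#' Three supported modes: the standard gene-level explanation of a class
#' logit (`class_logit` over `input_genes`), the interim-layer explanation of
#' a class logit in latent space (`class_logit` over `latent_mu`), and the
#' explanation of one latent dimension by the input genes (`latent_dim` over
#' `input_genes`). Class targets always explain the pre-activation logit,
#' never the softmax probability; latent targets explain the deterministic
#' mean `mu_j`.
#'
#' @param kind `"class_logit"` or `"latent_dim"`.
#' @param index Class label (character) or class index for `class_logit`;
#'   latent dimension index for `latent_dim`.
#' @param layer Feature space attributed over: `"input_genes"` or
#'   `"latent_mu"`.
#' @return A `target_spec`.
#' @export
target_spec <- function(kind = c("class_logit", "latent_dim"), index,
                        layer = c("input_genes", "latent_mu")) {
  kind <- match.arg(kind)
  layer <- match.arg(layer)
  if (kind == "latent_dim" && layer == "latent_mu") {
    stop("a latent dimension cannot be attributed over the latent layer")
  }
  structure(list(kind = kind, index = index, layer = layer),
            class = "target_spec")
}

#' Build a reference (background) set for attribution
#'
#' Reference profiles are the baseline against which activation differences
#' are measured; their choice changes which genes appear important. Supported
#' strategies: `random_train` (uniform seeded draw of `k_refs` training rows),
#' `phenotype_matched` (draw restricted to samples matching a filter, e.g.
#' normal tissue or the opposite sex) and `custom` (caller-supplied profiles).
#'
#' @param m An [expression_matrix()] to draw from (ignored for `custom`).
#' @param strategy Reference strategy.
#' @param k_refs Number of reference profiles (default 100).
#' @param phenotype_filter For `phenotype_matched`: either a logical vector
#'   over samples, or a named character vector of `column = value` pairs
#'   where `"class"` matches the class labels and other names match phenotype
#'   columns, e.g. `c(sex = "male")` or `c(class = "normal")`.
#' @param seed Seed for the draw.
#' @param profiles For `custom`: a matrix of reference profiles.
#' @return A `reference_set` with elements `profiles`, `strategy`, `seed`.
#' @export
build_reference_set <- function(m = NULL,
                                strategy = c("random_train",
                                             "phenotype_matched", "custom"),
                                k_refs = 100L, phenotype_filter = NULL,
                                seed = 1L, profiles = NULL) {
  strategy <- match.arg(strategy)
  if (strategy == "custom") {
    if (is.null(profiles)) stop("custom strategy requires profiles")
    profiles <- as.matrix(profiles)
    return(structure(list(profiles = profiles, strategy = strategy,
                          seed = seed), class = "reference_set"))
  }
  stopifnot(inherits(m, "expression_matrix"))
  pool <- seq_len(n_samples(m))
  if (strategy == "phenotype_matched") {
    if (is.null(phenotype_filter)) {
      stop("phenotype_matched requires a phenotype_filter")
    }
    if (is.logical(phenotype_filter)) {
      keep <- phenotype_filter
    } else {
      keep <- rep(TRUE, n_samples(m))
      for (col in names(phenotype_filter)) {
        vals <- if (col == "class") as.character(m$class_labels)
                else m$phenotypes[[col]]
        if (is.null(vals)) stop("unknown phenotype column: ", col)
        keep <- keep & vals == phenotype_filter[[col]]
      }
    }
    pool <- pool[keep]
    if (!length(pool)) stop("phenotype filter matches no samples")
  }
  withr::with_seed(seed, {
    take <- if (length(pool) <= k_refs) pool
            else sample(pool, k_refs)
  })
  structure(list(profiles = m$values[take, , drop = FALSE],
                 strategy = strategy, seed = seed,
                 sample_ids = m$sample_ids[take]),
            class = "reference_set")
}

.ref_profiles <- function(refs) {
  if (inherits(refs, "reference_set")) refs$profiles
  else if (inherits(refs, "expression_matrix")) refs$values
  else as.matrix(refs)
}

.resolve_class_index <- function(model, index) {
  if (is.character(index)) {
    i <- match(index, model$classes)
    if (is.na(i)) stop("unknown class label: ", index)
    i
  } else {
    i <- as.integer(index)
    if (i < 1L || i > length(model$classes)) stop("class index out of range")
    i
  }
}

# Resolve a model + target into (network, output index, feature ids) and map
# gene-space samples/references into the demanded feature space.
.attribution_context <- function(model, samples, refs, target) {
  stopifnot(inherits(target, "target_spec"))
  if (inherits(model, "mlp_network")) {
    x <- .as_input_matrix(samples, attr(model, "n_in"), "samples")
    ids <- colnames(x) %||% sprintf("F%04d", seq_len(ncol(x)))
    return(list(net = model, index = as.integer(target$index),
                x = x, r = .ref_profiles(refs), feature_ids = ids))
  }
  stopifnot(inherits(model, "vae_classifier"))
  x <- if (inherits(samples, "expression_matrix")) samples$values
       else as.matrix(rbind(samples))
  r <- .ref_profiles(refs)
  n_g <- length(model$gene_ids)
  d <- model$hyper$latent_dim
  if (target$layer == "latent_mu") {
    if (target$kind != "class_logit") stop("latent_mu layer expects a class target")
    if (ncol(x) == n_g) x <- encode(model, x)$mu
    if (ncol(r) == n_g) r <- encode(model, r)$mu
    if (ncol(x) != d || ncol(r) != d) {
      stop("latent-space features must have ", d, " dimensions")
    }
    list(net = .classifier_net(model),
         index = .resolve_class_index(model, target$index),
         x = x, r = r, feature_ids = sprintf("dim_%03d", seq_len(d)))
  } else if (target$kind == "class_logit") {
    list(net = .class_path_net(model),
         index = .resolve_class_index(model, target$index),
         x = x, r = r, feature_ids = model$gene_ids)
  } else {
    j <- as.integer(target$index)
    if (j < 1L || j > d) stop("latent dimension ", j, " out of range 1..", d)
    list(net = .encoder_net(model), index = j, x = x, r = r,
         feature_ids = model$gene_ids)
  }
}

#' Rescale-rule attribution for a declared target
#'
#' For each explained sample and each reference profile, contribution scores
#' are computed by backpropagating rescale-rule multipliers through the
#' relevant deterministic sub-network (encoder trunk to `mu`, classifier, or
#' their composition; the sampling node lies outside every explained path),
#' then averaged over the reference set. Per (sample, reference) pair the
#' scores satisfy summation-to-delta before averaging.
#'
#' @param model A trained `vae_classifier`, or a bare [mlp_network()] (then
#'   `target$index` is the raw output unit).
#' @param samples Samples to explain (matrix or [expression_matrix()]).
#' @param refs A [build_reference_set()] result, an expression matrix, or a
#'   plain matrix of reference profiles in the same feature space.
#' @param target A [target_spec()].
#' @return An `attribution_result`: `scores` (samples x features,
#'   reference-averaged), `delta_o` (`f(x) - mean_r f(r)` per sample),
#'   `target`, `reference` (strategy summary) and `max_rel_error`, the worst
#'   relative summation-to-delta violation observed.
#' @export
attribute <- function(model, samples, refs, target) {
  ctx <- .attribution_context(model, samples, refs, target)
  core <- attribute_network(ctx$net, ctx$x, ctx$r, ctx$index)
  colnames(core$scores) <- ctx$feature_ids
  structure(list(scores = core$scores, delta_o = core$delta_o,
                 outputs = core$outputs, ref_outputs = core$ref_outputs,
                 target = target,
                 reference = list(
                   strategy = if (inherits(refs, "reference_set"))
                     refs$strategy else "custom",
                   k_refs = nrow(ctx$r)),
                 method = "rescale",
                 max_rel_error = core$max_rel_error),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("<attribution_result> ", nrow(x$scores), " sample(s) x ",
      ncol(x$scores), " feature(s); method ", x$method,
      "; max summation-to-delta rel. error ",
      format(x$max_rel_error, digits = 3), "\n", sep = "")
  invisible(x)
}

.ranked_from_scores <- function(score, ids, provenance = list(),
                                direction = "descending") {
  ord <- if (direction == "descending") order(-score, ids) else order(score, ids)
  out <- data.frame(rank = seq_along(ord), gene_id = ids[ord],
                    score = score[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_gene_list", "data.frame"),
            provenance = provenance, direction = direction)
}

#' Aggregate attributions to a ranked feature list
#'
#' The absolute contribution of each feature is averaged over the selected
#' samples (absolute values prevent positive and negative scores from
#' cancelling), then features are sorted by decreasing score with a
#' deterministic tie-break on feature id.
#'
#' @param res An `attribution_result`.
#' @param sample_mask Optional logical or integer subset of samples
#'   (default: all).
#' @return A `ranked_gene_list` data frame with columns `rank`, `gene_id`,
#'   `score`.
#' @export
aggregate_abs_mean <- function(res, sample_mask = NULL) {
  stopifnot(inherits(res, "attribution_result"))
  s <- res$scores
  if (!is.null(sample_mask)) s <- s[sample_mask, , drop = FALSE]
  if (!nrow(s)) stop("sample mask selects no samples")
  sc <- colMeans(abs(s))
  .ranked_from_scores(sc, colnames(res$scores),
                      provenance = list(target = res$target,
                                        reference = res$reference,
                                        method = res$method,
                                        n_samples = nrow(s)))
}

#' @export
print.ranked_gene_list <- function(x, n = 10L, ...) {
  cat("<ranked_gene_list> ", nrow(x), " features (",
      attr(x, "direction") %||% "descending", " score)\n", sep = "")
  print.data.frame(utils::head(x, n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genes ranked by contribution to one class prediction
#'
#' Attributes the class's pre-activation logit over the input genes for the
#' given samples against the reference set, then aggregates by absolute mean.
#'
#' @param model A trained `vae_classifier`.
#' @param class_label The class to explain.
#' @param samples Samples of interest (typically samples of that class).
#' @param refs Reference set or matrix (gene space).
#' @return A `ranked_gene_list`.
#' @export
explain_class_by_genes <- function(model, class_label, samples, refs) {
  res <- attribute(model, samples, refs,
                   target_spec("class_logit", class_label, "input_genes"))
  aggregate_abs_mean(res)
}

#' Latent dimensions ranked by contribution to one class prediction
#'
#' Intercepts the classifier's input layer: samples and references are
#' encoded to `mu` space by the model and the class logit is attributed over
#' the latent dimensions. The returned list carries the integer dimension
#' order in `ranked_dims()`.
#'
#' @inheritParams explain_class_by_genes
#' @return A `ranked_gene_list` whose ids are `dim_###`.
#' @export
explain_class_by_latent <- function(model, class_label, samples, refs) {
  res <- attribute(model, samples, refs,
                   target_spec("class_logit", class_label, "latent_mu"))
  out <- aggregate_abs_mean(res)
  attr(out, "dim_index") <- as.integer(sub("dim_", "", out$gene_id))
  out
}

#' Integer dimension indices of a latent ranking, in rank order
#' @param ranked A ranking from [explain_class_by_latent()].
#' @return Integer vector.
#' @export
ranked_dims <- function(ranked) {
  idx <- attr(ranked, "dim_index")
  if (is.null(idx)) idx <- as.integer(sub("dim_", "", ranked$gene_id))
  idx
}

#' Genes ranked by contribution to one latent dimension
#'
#' The deterministic latent mean `mu_j` is the explained output; attribution
#' runs over the input genes.
#'
#' @param model A trained `vae_classifier`.
#' @param dim_index Latent dimension (1-based).
#' @param samples Samples of interest.
#' @param refs Reference set or matrix (gene space).
#' @return A `ranked_gene_list`.
#' @export
explain_latent_by_genes <- function(model, dim_index, samples, refs) {
  res <- attribute(model, samples, refs,
                   target_spec("latent_dim", dim_index, "input_genes"))
  aggregate_abs_mean(res)
}

#' Gradient-based baseline attribution methods
#'
#' Comparator methods for the rescale-rule engine: `saliency`
#' (`|df/dx_i|`), `input_x_gradient` (`x_i * df/dx_i`) and `gradient_shap`
#' (expected gradients: average over draws of `(x_i - r_i) * df/dx` at
#' `r + u (x - r)`, `u ~ U(0,1)`, `r` sampled from the references).
#'
#' @param method Baseline method name.
#' @param model A `vae_classifier` or bare [mlp_network()].
#' @param samples Samples to explain.
#' @param refs References (required for `gradient_shap`).
#' @param target A [target_spec()].
#' @param n_draws Monte-Carlo draws for `gradient_shap` (default 50).
#' @param seed Seed for the draws.
#' @return An `attribution_result` (its `delta_o` is `NA` for the purely
#'   gradient-based methods, which have no reference).
#' @export
baseline_attribution <- function(method = c("saliency", "input_x_gradient",
                                            "gradient_shap"),
                                 model, samples, refs = NULL, target,
                                 n_draws = 50L, seed = 1L) {
  method <- match.arg(method)
  ctx <- .attribution_context(model, samples, refs %||% samples, target)
  x <- .as_input_matrix(ctx$x, attr(ctx$net, "n_in"), "samples")
  scores <- switch(method,
    saliency = .net_saliency(ctx$net, x, ctx$index),
    input_x_gradient = .net_input_x_gradient(ctx$net, x, ctx$index),
    gradient_shap = {
      if (is.null(refs)) stop("gradient_shap requires references")
      .net_gradient_shap(ctx$net, x, ctx$r, ctx$index,
                         n_draws = n_draws, seed = seed)
    })
  colnames(scores) <- ctx$feature_ids
  delta <- if (method == "gradient_shap") {
    net_output(ctx$net, x)[, ctx$index] -
      mean(net_output(ctx$net, ctx$r)[, ctx$index])
  } else rep(NA_real_, nrow(x))
  structure(list(scores = scores, delta_o = delta,
                 target = target,
                 reference = list(strategy = if (method == "gradient_shap")
                   "sampled" else "none", k_refs = if (is.null(refs)) 0L
                   else nrow(.ref_profiles(refs))),
                 method = method, max_rel_error = NA_real_),
            class = "attribution_result")
}
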