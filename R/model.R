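# VAE embedding network with an attached classifier head, trained in two
# phases (unsupervised ELBO, then ELBO + cross-entropy). The classifier
# consumes the latent mean vector mu directly, so prediction and attribution
# are deterministic; the sampling node z = mu + sigma*eps is used only by the
# decoder during training.

#' Hyperparameters for the VAE classifier
#'
#' @param latent_dim Latent bottleneck width (default 128).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param epochs_unsupervised Phase-1 epochs optimising the VAE loss alone
#'   (default 50).
#' @param epochs_supervised Phase-2 epochs optimising the weighted total loss
#'   (default 100).
#' @param alpha,beta Weights of the VAE and classification losses in phase 2
#'   (phase 1 is always `alpha = 1, beta = 0`).
#' @param encoder_hidden Integer vector of encoder hidden-layer widths (ReLU);
#'   the decoder mirrors it.
#' @param classifier_hidden Classifier hidden widths; default `c(128, 64)`,
#'   two ReLU hidden layers.
#' @param recon_loss `"bce"` (elementwise binary cross-entropy, the default
#'   for inputs in `[0,1]`) or `"mse"`.
#' @param seed Integer seed controlling initialisation, shuffling and the
#'   reparameterization noise.
#' @return A `vae_hyperparams` object.
#' @export
vae_hyperparams <- function(latent_dim = 128L, learning_rate = 1e-3,
                            batch_size = 32L, epochs_unsupervised = 50L,
                            epochs_supervised = 100L, alpha = 1, beta = 1,
                            encoder_hidden = 1024L,
                            classifier_hidden = c(128L, 64L),
                            recon_loss = c("bce", "mse"), seed = 1L) {
  recon_loss <- match.arg(recon_loss)
  h <- list(latent_dim = as.integer(latent_dim),
            learning_rate = learning_rate,
            batch_size = as.integer(batch_size),
            epochs_unsupervised = as.integer(epochs_unsupervised),
            epochs_supervised = as.integer(epochs_supervised),
            alpha = alpha, beta = beta,
            encoder_hidden = as.integer(encoder_hidden),
            classifier_hidden = as.integer(classifier_hidden),
            recon_loss = recon_loss, seed = as.integer(seed))
  stopifnot(h$latent_dim > 0, h$learning_rate > 0, h$batch_size > 0,
            h$epochs_unsupervised >= 0, h$epochs_supervised >= 0,
            h$alpha >= 0, h$beta >= 0, all(h$encoder_hidden > 0),
            all(h$classifier_hidden > 0))
  structure(h, class = "vae_hyperparams")
}

#' Reparameterization trick
#'
#' `z = mu + sigma * eps`, elementwise, which moves the sampling outside the
#' differentiated path.
#'
#' @param mu,sigma,eps Numeric vectors of equal length; `sigma > 0`.
#' @return The latent draw `z`.
#' @export
reparameterize <- function(mu, sigma, eps) {
  if (length(mu) != length(sigma) || length(mu) != length(eps)) {
    stop("mu, sigma and eps must have equal length")
  }
  if (any(sigma <= 0)) stop("sigma must be positive elementwise")
  mu + sigma * eps
}

#' KL divergence from N(mu, diag(sigma^2)) to the unit Gaussian
#'
#' Closed form `sum_j 0.5 * (sigma_j^2 + mu_j^2 - 1 - 2 log sigma_j)`.
#'
#' @param mu,sigma Numeric vectors of equal length; `sigma > 0`.
#' @return Non-negative scalar.
#' @export
kl_unit_gaussian <- function(mu, sigma) {
  if (length(mu) != length(sigma)) stop("mu and sigma must have equal length")
  if (any(sigma <= 0)) stop("sigma must be positive elementwise")
  sum(0.5 * (sigma^2 + mu^2 - 1 - 2 * log(sigma)))
}

.bce_elementwise <- function(x, p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(x * log(p) + (1 - x) * log1p(-p))
}

#' Negative ELBO of a batch
#'
#' Reconstruction term (elementwise binary cross-entropy summed over genes,
#' averaged over samples) plus the KL term (summed over latent dimensions,
#' averaged over samples). `recon_weight = 0` isolates the KL term.
#'
#' @param x Input batch in `[0,1]` (matrix or vector).
#' @param x_recon Reconstruction probabilities, same shape.
#' @param mu,sigma Latent Gaussian parameters per sample (matrix rows or
#'   vectors); `sigma > 0`.
#' @param recon_weight Weight on the reconstruction term (default 1).
#' @return Scalar loss.
#' @export
vae_loss <- function(x, x_recon, mu, sigma, recon_weight = 1) {
  x <- rbind(x); x_recon <- rbind(x_recon)
  mu <- rbind(mu); sigma <- rbind(sigma)
  if (any(x < 0 | x > 1)) stop("x must lie in [0, 1]")
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (!identical(dim(x), dim(x_recon))) stop("x and x_recon shape mismatch")
  recon <- mean(rowSums(.bce_elementwise(x, x_recon)))
  kl <- mean(rowSums(0.5 * (sigma^2 + mu^2 - 1 - 2 * log(sigma))))
  recon_weight * recon + kl
}

.softmax <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

#' Mean categorical cross-entropy of logits against labels
#'
#' @param logits Matrix, one row per sample, one column per class.
#' @param y Labels: a factor, or character/integer resolved against `classes`.
#' @param classes Class vocabulary (defaults to `levels(y)` or the column
#'   names of `logits`).
#' @return Scalar mean cross-entropy of `softmax(logits)` against `y`.
#' @export
classification_loss <- function(logits, y, classes = NULL) {
  logits <- rbind(logits)
  if (is.null(classes)) {
    classes <- if (is.factor(y)) levels(y) else colnames(logits)
  }
  if (is.null(classes) && is.numeric(y)) classes <- seq_len(ncol(logits))
  yi <- if (is.numeric(y) && !is.factor(y)) as.integer(y)
        else match(as.character(y), as.character(classes))
  if (anyNA(yi) || any(yi < 1L | yi > ncol(logits))) {
    stop("label outside the class vocabulary")
  }
  if (length(yi) != nrow(logits)) stop("one logit row per sample required")
  p <- .softmax(logits)
  -mean(log(pmax(p[cbind(seq_along(yi), yi)], 1e-300)))
}

#' Weighted total loss
#'
#' @param l_vae,l_class Component losses.
#' @param alpha,beta Non-negative weights.
#' @return `alpha * l_vae + beta * l_class`.
#' @export
total_loss <- function(l_vae, l_class, alpha, beta) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  alpha * l_vae + beta * l_class
}

# ---- parameter initialisation and Adam --------------------------------------

.init_dense <- function(n_in, n_out, scale = sqrt(2 / n_in)) {
  list(W = matrix(stats::rnorm(n_in * n_out, sd = scale), n_in, n_out),
       b = numeric(n_out))
}

.init_params <- function(n_genes, hyper, n_classes) {
  eh <- hyper$encoder_hidden
  enc <- list(); n_in <- n_genes
  for (w in eh) { enc[[length(enc) + 1L]] <- .init_dense(n_in, w); n_in <- w }
  mu <- .init_dense(n_in, hyper$latent_dim, scale = sqrt(1 / n_in))
  lv <- .init_dense(n_in, hyper$latent_dim, scale = 0.01 * sqrt(1 / n_in))
  dec <- list(); n_in <- hyper$latent_dim
  for (w in rev(eh)) { dec[[length(dec) + 1L]] <- .init_dense(n_in, w); n_in <- w }
  dec_out <- .init_dense(n_in, n_genes, scale = sqrt(1 / n_in))
  cls <- list(); n_in <- hyper$latent_dim
  for (w in hyper$classifier_hidden) {
    cls[[length(cls) + 1L]] <- .init_dense(n_in, w); n_in <- w
  }
  cls_out <- .init_dense(n_in, n_classes, scale = sqrt(1 / n_in))
  list(enc = enc, mu = mu, lv = lv, dec = dec, dec_out = dec_out,
       cls = cls, cls_out = cls_out)
}

.zeros_like <- function(p) {
  if (is.numeric(p)) return(p * 0)
  lapply(p, .zeros_like)
}

# Adam runs in compiled code (see src/adam.cpp) and updates the parameter
# and moment arrays in place; the R side only owns the allocation.

# ---- forward/backward through the ReLU trunks -------------------------------

.trunk_forward <- function(layers, X) {
  k <- length(layers)
  pres <- vector("list", k); ins <- vector("list", k)
  H <- X
  for (i in seq_len(k)) {
    ins[[i]] <- H
    pre <- sweep(H %*% layers[[i]]$W, 2L, layers[[i]]$b, "+")
    pres[[i]] <- pre
    H <- pmax(pre, 0)
  }
  list(out = H, pres = pres, ins = ins)
}

.trunk_backward <- function(layers, cache, dOut) {
  g <- vector("list", length(layers))
  d <- dOut
  for (i in rev(seq_along(layers))) {
    dpre <- d * (cache$pres[[i]] > 0)
    g[[i]] <- list(W = crossprod(cache$ins[[i]], dpre), b = colSums(dpre))
    d <- tcrossprod(dpre, layers[[i]]$W)
  }
  list(dIn = d, grads = g)
}

# One minibatch: losses and gradients for total = alpha*(recon+kl) + beta*ce.
.model_step <- function(p, Xb, yi, alpha, beta, recon_loss) {
  nb <- nrow(Xb)
  enc <- .trunk_forward(p$enc, Xb)
  mu <- sweep(enc$out %*% p$mu$W, 2L, p$mu$b, "+")
  lv <- sweep(enc$out %*% p$lv$W, 2L, p$lv$b, "+")
  lv <- pmin(pmax(lv, -10), 10)
  sigma <- exp(0.5 * lv)
  epsm <- matrix(stats::rnorm(length(mu)), nrow(mu))
  z <- mu + sigma * epsm
  dec <- .trunk_forward(p$dec, z)
  L <- sweep(dec$out %*% p$dec_out$W, 2L, p$dec_out$b, "+")
  if (recon_loss == "bce") {
    recon <- mean(rowSums(pmax(L, 0) - L * Xb + log1p(exp(-abs(L)))))
    dL <- alpha * (1 / (1 + exp(-L)) - Xb) / nb
  } else {
    xr <- 1 / (1 + exp(-L))
    recon <- mean(rowSums((xr - Xb)^2))
    dL <- alpha * 2 * (xr - Xb) * xr * (1 - xr) / nb
  }
  kl <- mean(rowSums(0.5 * (sigma^2 + mu^2 - 1 - lv)))

  g_dec_out <- list(W = crossprod(dec$out, dL), b = colSums(dL))
  decb <- .trunk_backward(p$dec, dec, tcrossprod(dL, p$dec_out$W))
  dz <- decb$dIn
  dmu <- dz + alpha * mu / nb
  dlv <- dz * epsm * (0.5 * sigma) + alpha * 0.5 * (sigma^2 - 1) / nb

  ce <- NA_real_
  if (beta > 0) {
    cls <- .trunk_forward(p$cls, mu)
    logits <- sweep(cls$out %*% p$cls_out$W, 2L, p$cls_out$b, "+")
    P <- .softmax(logits)
    ce <- -mean(log(pmax(P[cbind(seq_len(nb), yi)], 1e-300)))
    dlg <- P
    dlg[cbind(seq_len(nb), yi)] <- dlg[cbind(seq_len(nb), yi)] - 1
    dlg <- beta * dlg / nb
    g_cls_out <- list(W = crossprod(cls$out, dlg), b = colSums(dlg))
    clsb <- .trunk_backward(p$cls, cls, tcrossprod(dlg, p$cls_out$W))
    g_cls <- clsb$grads
    dmu <- dmu + clsb$dIn
  } else {
    g_cls <- lapply(p$cls, function(l) list(W = l$W * 0, b = l$b * 0))
    g_cls_out <- list(W = p$cls_out$W * 0, b = p$cls_out$b * 0)
  }

  g_mu <- list(W = crossprod(enc$out, dmu), b = colSums(dmu))
  g_lv <- list(W = crossprod(enc$out, dlv), b = colSums(dlv))
  encb <- .trunk_backward(p$enc, enc,
                          tcrossprod(dmu, p$mu$W) + tcrossprod(dlv, p$lv$W))
  list(grads = list(enc = encb$grads, mu = g_mu, lv = g_lv,
                    dec = decb$grads, dec_out = g_dec_out,
                    cls = g_cls, cls_out = g_cls_out),
       recon = recon, kl = kl, class = ce)
}

#' Train the VAE classifier
#'
#' Phase 1 optimises the VAE loss alone for `epochs_unsupervised` epochs
#' (`alpha = 1, beta = 0`); phase 2 optimises the weighted total loss for
#' `epochs_supervised` epochs. Optimisation is Adam with seeded minibatch
#' shuffling; the run is fully reproducible from `hyper$seed`.
#'
#' @param m A complete [expression_matrix()] with values in `[0,1]`, carrying
#'   class labels if a supervised phase is requested.
#' @param hyper A [vae_hyperparams()].
#' @param verbose Print per-epoch losses.
#' @return A `vae_classifier`: parameters, class vocabulary, gene ids, the
#'   per-epoch training log (`$history`) and the hyperparameters.
#' @export
train_vae_classifier <- function(m, hyper = vae_hyperparams(), verbose = FALSE) {
  stopifnot(inherits(m, "expression_matrix"))
  X <- m$values
  if (anyNA(X)) stop("matrix has missing values; run impute_missing() first")
  if (any(X < 0 | X > 1)) stop("matrix values must lie in [0, 1]")
  supervised <- hyper$epochs_supervised > 0L && hyper$beta > 0
  if (supervised && is.null(m$class_labels)) {
    stop("class labels are required for the supervised phase")
  }
  classes <- if (!is.null(m$class_labels)) levels(m$class_labels) else "none"
  yi <- if (!is.null(m$class_labels)) as.integer(m$class_labels)
        else rep(1L, nrow(X))
  n <- nrow(X)
  history <- list()
  withr::with_seed(hyper$seed, {
    params <- .init_params(ncol(X), hyper, length(classes))
    state <- list(m = .zeros_like(params), v = .zeros_like(params))
    t_step <- 0L
    run_phase <- function(phase, epochs, alpha, beta) {
      for (ep in seq_len(epochs)) {
        ord <- sample.int(n)
        starts <- seq(1L, n, by = hyper$batch_size)
        acc <- c(recon = 0, kl = 0, class = 0); nb_used <- 0L
        for (s in starts) {
          idx <- ord[s:min(s + hyper$batch_size - 1L, n)]
          st <- .model_step(params, X[idx, , drop = FALSE], yi[idx],
                            alpha, beta, hyper$recon_loss)
          tot <- alpha * (st$recon + st$kl) +
            (if (beta > 0) beta * st$class else 0)
          if (!is.finite(tot)) {
            stop("non-finite loss in phase ", phase, ", epoch ", ep,
                 ", batch starting at sample ", s)
          }
          t_step <<- t_step + 1L
          adam_update_(params, st$grads, state$m, state$v,
                       hyper$learning_rate, t_step, 0.9, 0.999, 1e-8)
          acc <- acc + c(st$recon, st$kl,
                         if (beta > 0) st$class else 0)
          nb_used <- nb_used + 1L
        }
        acc <- acc / nb_used
        history[[length(history) + 1L]] <<- data.frame(
          phase = phase, epoch = ep, recon = acc[["recon"]], kl = acc[["kl"]],
          class = if (beta > 0) acc[["class"]] else NA_real_,
          total = alpha * (acc[["recon"]] + acc[["kl"]]) +
            (if (beta > 0) beta * acc[["class"]] else 0))
        if (verbose) {
          message(sprintf("phase %d epoch %3d  recon %.3f  kl %.3f  ce %s",
                          phase, ep, acc[["recon"]], acc[["kl"]],
                          if (beta > 0) sprintf("%.4f", acc[["class"]]) else "-"))
        }
      }
    }
    run_phase(1L, hyper$epochs_unsupervised, 1, 0)
    run_phase(2L, hyper$epochs_supervised, hyper$alpha, hyper$beta)
  })
  structure(list(params = params, hyper = hyper, classes = classes,
                 gene_ids = m$gene_ids, history = do.call(rbind, history),
                 ablated_dims = integer(0)),
            class = "vae_classifier")
}

#' @export
print.vae_classifier <- function(x, ...) {
  cat("<vae_classifier> ", length(x$gene_ids), " genes -> latent ",
      x$hyper$latent_dim, " -> ", length(x$classes), " classes",
      if (length(x$ablated_dims))
        paste0("; ablated dims: ", paste(x$ablated_dims, collapse = ",")),
      "\n", sep = "")
  invisible(x)
}

.model_input <- function(model, x) {
  if (inherits(x, "expression_matrix")) x <- x$values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$gene_ids)) {
    stop("input has ", ncol(x), " genes but the model expects ",
         length(model$gene_ids))
  }
  x
}

#' Encode samples to the latent Gaussian parameters
#'
#' @param model A `vae_classifier`.
#' @param x Matrix (samples x genes) or [expression_matrix()].
#' @return List with matrices `mu` and `sigma` (`n x latent_dim`).
#' @export
encode <- function(model, x) {
  stopifnot(inherits(model, "vae_classifier"))
  X <- .model_input(model, x)
  p <- model$params
  H <- .trunk_forward(p$enc, X)$out
  mu <- sweep(H %*% p$mu$W, 2L, p$mu$b, "+")
  lv <- pmin(pmax(sweep(H %*% p$lv$W, 2L, p$lv$b, "+"), -10), 10)
  list(mu = mu, sigma = exp(0.5 * lv))
}

.apply_ablation <- function(mu, dims) {
  if (!length(dims)) return(mu)
  sub <- mu[, dims, drop = FALSE]
  pos <- sub > 0
  neg <- sub < 0         # mu exactly 0 is left unchanged
  sub[pos] <- -1
  sub[neg] <- 1
  mu[, dims] <- sub
  mu
}

.classify_mu <- function(model, mu) {
  p <- model$params
  H <- .trunk_forward(p$cls, mu)$out
  sweep(H %*% p$cls_out$W, 2L, p$cls_out$b, "+")
}

#' Predict classes from expression profiles
#'
#' Deterministic: the classifier consumes the latent mean `mu` directly (no
#' sampling). If the model carries an ablation spec (see [ablate()]), the
#' sign-flip is applied to the listed latent dimensions before classification.
#'
#' @param object A `vae_classifier`.
#' @param x Matrix (samples x genes) or [expression_matrix()].
#' @param ... Unused.
#' @return List with `class` (factor), `probabilities` (rows sum to 1),
#'   `logits` (pre-activation outputs, the attribution target) and `mu`.
#' @export
predict.vae_classifier <- function(object, x, ...) {
  mu <- encode(object, x)$mu
  mu <- .apply_ablation(mu, object$ablated_dims)
  logits <- .classify_mu(object, mu)
  colnames(logits) <- object$classes
  probs <- .softmax(logits)
  colnames(probs) <- object$classes
  cls <- factor(object$classes[max.col(logits, ties.method = "first")],
                levels = object$classes)
  list(class = cls, probabilities = probs, logits = logits, mu = mu)
}

#' Classification accuracy on a labelled matrix
#' @param model A `vae_classifier`.
#' @param m A labelled [expression_matrix()].
#' @return Fraction of correctly classified samples.
#' @export
classification_accuracy <- function(model, m) {
  stopifnot(!is.null(m$class_labels))
  pred <- predict(model, m)$class
  mean(as.character(pred) == as.character(m$class_labels))
}

#' Stratified train/test split
#'
#' @param labels Per-sample labels (factor or character).
#' @param test_fraction Fraction held out per class (default 0.2).
#' @param seed Seed for the shuffling.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  labels <- as.factor(labels)
  withr::with_seed(seed, {
    test <- unlist(lapply(levels(labels), function(l) {
      idx <- which(labels == l)
      sample(idx, max(1L, round(length(idx) * test_fraction)))
    }), use.names = FALSE)
  })
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Save / load a trained model
#' @param model A `vae_classifier`.
#' @param path Checkpoint file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "vae_classifier"))
  model
}

# ---- subnetworks used by the attribution engine -----------------------------

.dense_relu_layers <- function(trunk) {
  out <- list()
  for (l in trunk) {
    out <- c(out, list(dense_layer(l$W, l$b), activation_layer("relu")))
  }
  out
}

# genes -> mu (deterministic encoder head)
.encoder_net <- function(model) {
  p <- model$params
  mlp_network(c(.dense_relu_layers(p$enc),
                list(dense_layer(p$mu$W, p$mu$b))))
}

# mu -> class logits
.classifier_net <- function(model) {
  p <- model$params
  mlp_network(c(.dense_relu_layers(p$cls),
                list(dense_layer(p$cls_out$W, p$cls_out$b))))
}

# genes -> class logits through mu
.class_path_net <- function(model) {
  p <- model$params
  mlp_network(c(.dense_relu_layers(p$enc),
                list(dense_layer(p$mu$W, p$mu$b)),
                .dense_relu_layers(p$cls),
                list(dense_layer(p$cls_out$W, p$cls_out$b))))
}
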