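# Minimal feed-forward network substrate: dense + elementwise-activation layers,
# a forward pass that retains per-layer inputs, reverse-mode gradients, and the
# rescale-rule (DeepLIFT/Deep-SHAP) multiplier backpropagation used by the
# attribution engine. Everything is plain matrices so BLAS does the work.

.activations <- list(
  relu = list(
    f  = function(x) pmax(x, 0),
    df = function(x) (x > 0) * 1
  ),
  sigmoid = list(
    f  = function(x) 1 / (1 + exp(-x)),
    df = function(x) { s <- 1 / (1 + exp(-x)); s * (1 - s) }
  ),
  tanh = list(
    f  = function(x) tanh(x),
    df = function(x) 1 - tanh(x)^2
  ),
  identity = list(
    f  = function(x) x,
    df = function(x) { x[] <- 1; x }
  )
)

#' Dense (fully connected) layer
#'
#' @param W Weight matrix, `n_in x n_out`.
#' @param b Bias vector of length `n_out`; defaults to zeros.
#' @return An `mlp_layer` object.
#' @export
dense_layer <- function(W, b = NULL) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  if (is.null(b)) b <- numeric(ncol(W))
  b <- as.numeric(b)
  if (length(b) != ncol(W)) {
    stop("bias length (", length(b), ") must equal ncol(W) (", ncol(W), ")")
  }
  if (any(!is.finite(W)) || any(!is.finite(b))) stop("non-finite layer parameters")
  structure(list(type = "dense", W = W, b = b), class = "mlp_layer")
}

#' Elementwise activation layer
#'
#' @param fun One of `"relu"`, `"sigmoid"`, `"tanh"`, `"identity"`.
#' @return An `mlp_layer` object.
#' @export
activation_layer <- function(fun = c("relu", "sigmoid", "tanh", "identity")) {
  fun <- match.arg(fun)
  structure(list(type = "activation", fun = fun), class = "mlp_layer")
}

#' Assemble a feed-forward network from layers
#'
#' Layers are applied left to right. Consecutive dense layers must have
#' compatible shapes; activation layers are shape-preserving.
#'
#' @param ... `mlp_layer` objects, or a single list of them.
#' @return An `mlp_network`.
#' @export
mlp_network <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1L]]) &&
      !inherits(layers[[1L]], "mlp_layer")) {
    layers <- layers[[1L]]
  }
  if (!length(layers)) stop("a network needs at least one layer")
  ok <- vapply(layers, inherits, logical(1), "mlp_layer")
  if (!all(ok)) stop("all arguments must be mlp_layer objects")
  dense <- which(vapply(layers, function(l) l$type == "dense", logical(1)))
  if (!length(dense)) stop("a network needs at least one dense layer")
  for (i in seq_along(dense)[-1L]) {
    a <- layers[[dense[i - 1L]]]; b <- layers[[dense[i]]]
    if (ncol(a$W) != nrow(b$W)) {
      stop("incompatible dense layers: ", ncol(a$W), " outputs feed ",
           nrow(b$W), " inputs")
    }
  }
  structure(list(layers = layers),
            class = "mlp_network",
            n_in  = nrow(layers[[dense[1L]]]$W),
            n_out = ncol(layers[[dense[length(dense)]]]$W))
}

#' @export
print.mlp_network <- function(x, ...) {
  cat("<mlp_network> ", attr(x, "n_in"), " -> ", attr(x, "n_out"), " features, ",
      length(x$layers), " layers\n", sep = "")
  invisible(x)
}

.as_input_matrix <- function(x, n_in, what = "input") {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (ncol(x) != n_in) {
    stop(what, " has ", ncol(x), " features but the network expects ", n_in)
  }
  x
}

#' Forward pass retaining per-layer inputs
#'
#' @param net An `mlp_network`.
#' @param x Input matrix (`n_samples x n_in`) or a single vector.
#' @return List with `output` (matrix `n_samples x n_out`) and `inputs`,
#'   the matrix fed into each layer (needed for multiplier backprop).
#' @export
net_forward <- function(net, x) {
  stopifnot(inherits(net, "mlp_network"))
  h <- .as_input_matrix(x, attr(net, "n_in"))
  inputs <- vector("list", length(net$layers))
  for (k in seq_along(net$layers)) {
    inputs[[k]] <- h
    ly <- net$layers[[k]]
    h <- if (ly$type == "dense") {
      sweep(h %*% ly$W, 2L, ly$b, "+")
    } else {
      .activations[[ly$fun]]$f(h)
    }
  }
  list(output = h, inputs = inputs)
}

#' Network output
#'
#' @inheritParams net_forward
#' @return Matrix of outputs, one row per sample.
#' @export
net_output <- function(net, x) net_forward(net, x)$output

# Backpropagate multipliers from a scalar output unit down to the inputs.
# mode "rescale": DeepLIFT rescale rule -- the multiplier through an
# elementwise nonlinearity is the chord slope (f(a) - f(a_ref)) / (a - a_ref),
# falling back to the local derivative when |a - a_ref| < fallback_eps.
# mode "gradient": plain reverse-mode differentiation (slope = f'(a)).
.net_multipliers <- function(net, inputs_x, inputs_r = NULL, target,
                             mode = c("rescale", "gradient"),
                             fallback_eps = 1e-7) {
  mode <- match.arg(mode)
  n <- nrow(inputs_x[[1L]])
  n_out <- attr(net, "n_out")
  if (target < 1L || target > n_out) {
    stop("target index ", target, " out of range 1..", n_out)
  }
  M <- matrix(0, n, n_out)
  M[, target] <- 1
  for (k in rev(seq_along(net$layers))) {
    ly <- net$layers[[k]]
    if (ly$type == "dense") {
      M <- tcrossprod(M, ly$W)
    } else {
      act <- .activations[[ly$fun]]
      a <- inputs_x[[k]]
      if (mode == "gradient") {
        M <- M * act$df(a)
      } else {
        ar <- inputs_r[[k]]
        if (nrow(ar) == 1L && n > 1L) ar <- ar[rep.int(1L, n), , drop = FALSE]
        da <- a - ar
        slope <- (act$f(a) - act$f(ar)) / da
        fall <- abs(da) < fallback_eps | !is.finite(slope)
        if (any(fall)) slope[fall] <- act$df(a)[fall]
        M <- M * slope
      }
    }
  }
  M
}

#' Rescale-rule attribution over a network
#'
#' Computes difference-from-reference contribution scores for one scalar output
#' unit by backpropagating rescale-rule multipliers (the DeepLIFT rescale rule,
#' as used by Deep SHAP). For each (sample, reference) pair the contributions
#' satisfy summation-to-delta: they sum to `f(x) - f(r)` exactly up to floating
#' point; contributions are then averaged over the reference set.
#'
#' @param net An `mlp_network`.
#' @param x Samples to explain (`n x n_in`).
#' @param refs Reference profiles (`k x n_in`); a vector is one reference.
#' @param target Index of the output unit to explain.
#' @param fallback_eps Threshold on `|a - a_ref|` below which the chord slope
#'   is replaced by the local derivative (0/0 guard).
#' @return List with `scores` (`n x n_in`, reference-averaged contributions),
#'   `delta_o` (`f(x) - mean_r f(r)` per sample), `outputs` (`f(x)` per
#'   sample), `ref_outputs` (`f(r)` per reference) and `max_rel_error`, the
#'   worst per-(sample, reference) relative violation of summation-to-delta.
#' @export
attribute_network <- function(net, x, refs, target, fallback_eps = 1e-7) {
  stopifnot(inherits(net, "mlp_network"))
  n_in <- attr(net, "n_in")
  x <- .as_input_matrix(x, n_in, "samples")
  refs <- .as_input_matrix(refs, n_in, "references")
  fx <- net_forward(net, x)
  out_x <- fx$output[, target]
  k <- nrow(refs)
  scores <- matrix(0, nrow(x), n_in)
  ref_outputs <- numeric(k)
  max_rel <- 0
  for (j in seq_len(k)) {
    fr <- net_forward(net, refs[j, , drop = FALSE])
    ref_outputs[j] <- fr$output[1L, target]
    M <- .net_multipliers(net, fx$inputs, fr$inputs, target,
                          mode = "rescale", fallback_eps = fallback_eps)
    contrib <- M * sweep(x, 2L, refs[j, ], "-")
    delta_jr <- out_x - ref_outputs[j]
    rel <- max(abs(rowSums(contrib) - delta_jr) / (abs(delta_jr) + 1e-6))
    if (rel > max_rel) max_rel <- rel
    scores <- scores + contrib
  }
  scores <- scores / k
  colnames(scores) <- colnames(x)
  list(scores = scores,
       delta_o = out_x - mean(ref_outputs),
       outputs = out_x,
       ref_outputs = ref_outputs,
       max_rel_error = max_rel)
}

#' Gradient of one output unit with respect to the inputs
#'
#' @inheritParams attribute_network
#' @return Matrix `n x n_in` of partial derivatives.
#' @export
net_gradient <- function(net, x, target) {
  stopifnot(inherits(net, "mlp_network"))
  x <- .as_input_matrix(x, attr(net, "n_in"), "samples")
  fx <- net_forward(net, x)
  .net_multipliers(net, fx$inputs, NULL, target, mode = "gradient")
}

# Baseline attribution cores (gradient-based comparators).
.net_saliency <- function(net, x, target) abs(net_gradient(net, x, target))

.net_input_x_gradient <- function(net, x, target) {
  x <- .as_input_matrix(x, attr(net, "n_in"), "samples")
  x * net_gradient(net, x, target)
}

# Expected-gradients style GradientSHAP: average over draws of
# (x - r) * grad f evaluated at r + u (x - r), u ~ U(0,1), r sampled from refs.
.net_gradient_shap <- function(net, x, refs, target, n_draws = 50L, seed = 1L) {
  n_in <- attr(net, "n_in")
  x <- .as_input_matrix(x, n_in, "samples")
  refs <- .as_input_matrix(refs, n_in, "references")
  n <- nrow(x)
  acc <- matrix(0, n, n_in)
  withr::with_seed(seed, {
    for (d in seq_len(n_draws)) {
      ridx <- sample.int(nrow(refs), n, replace = TRUE)
      u <- stats::runif(n)
      r <- refs[ridx, , drop = FALSE]
      diff <- x - r
      point <- r + diff * u
      acc <- acc + diff * net_gradient(net, point, target)
    }
  })
  acc / n_draws
}

# Effective linear map of a purely linear network (dense/identity layers only);
# used as the closed-form oracle target for attribution tests.
.net_effective_weights <- function(net) {
  W <- NULL
  for (ly in net$layers) {
    if (ly$type == "dense") {
      W <- if (is.null(W)) ly$W else W %*% ly$W
    } else if (ly$fun != "identity") {
      stop("network is not purely linear")
    }
  }
  W
}
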