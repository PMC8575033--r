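# Shared fixtures, built once per test run and cached.

small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(synthetic_spec(
        n_samples = 240L, n_genes = 300L, n_classes = 3L,
        planted_per_class = 12L, effect_size = 0.4, noise_sd = 0.1,
        na_rate = 0, seed = 42L))
    }
    cache
  }
})

# A quickly trained model on the small dataset (seconds, not minutes);
# shared by the attribution / latent / evaluation unit tests.
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- small_dataset()
      h <- vae_hyperparams(latent_dim = 8L, encoder_hidden = 64L,
                           epochs_unsupervised = 10L, epochs_supervised = 30L,
                           seed = 7L)
      cache <<- train_vae_classifier(ds$matrix, h)
    }
    cache
  }
})

# Random small network: 1-3 hidden layers, ReLU or sigmoid activations.
random_net <- function(seed, n_in = 6L, n_out = 2L) {
  withr::with_seed(seed, {
    widths <- sample(3:8, sample(1:3, 1L))
    layers <- list()
    prev <- n_in
    for (w in widths) {
      layers <- c(layers,
                  list(dense_layer(matrix(rnorm(prev * w), prev, w), rnorm(w)),
                       activation_layer(sample(c("relu", "sigmoid"), 1L))))
      prev <- w
    }
    layers <- c(layers,
                list(dense_layer(matrix(rnorm(prev * n_out), prev, n_out),
                                 rnorm(n_out))))
    mlp_network(layers)
  })
}

# Purely linear network of the given depth.
random_linear_net <- function(seed, n_in = 5L, n_out = 1L, depth = 3L) {
  withr::with_seed(seed, {
    layers <- list()
    prev <- n_in
    widths <- c(sample(3:7, depth - 1L, replace = TRUE), n_out)
    for (w in widths) {
      layers <- c(layers,
                  list(dense_layer(matrix(rnorm(prev * w), prev, w), rnorm(w))))
      prev <- w
    }
    mlp_network(layers)
  })
}

expr_subset <- function(em, rows) {
  expression_matrix(em$values[rows, , drop = FALSE],
                    gene_ids = em$gene_ids,
                    sample_ids = em$sample_ids[rows],
                    class_labels = if (!is.null(em$class_labels))
                      em$class_labels[rows],
                    phenotypes = if (!is.null(em$phenotypes))
                      em$phenotypes[rows, , drop = FALSE])
}
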