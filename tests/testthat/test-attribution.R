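# The rescale-rule attribution engine: closed forms on linear networks,
# summation-to-delta on nonlinear ones, aggregation, the multi-level
# explanation modes, reference strategies and baseline methods.

test_that("a single linear layer attributes w * (x - r) exactly", {
  w <- c(2, -1, 0.5)
  net <- mlp_network(dense_layer(matrix(w, 3, 1), b = 4))
  x <- c(1, 2, 3); r <- c(0, 1, -1)
  res <- attribute_network(net, x, r, target = 1L)
  expect_equal(as.vector(res$scores), w * (x - r))
  expect_equal(res$delta_o, sum(w * (x - r)))
})

test_that("deep purely linear networks reduce to the effective weight map", {
  for (seed in 1:8) {
    net <- random_linear_net(seed, n_in = 5L, depth = sample(2:5, 1))
    w_eff <- omixplain:::.net_effective_weights(net)[, 1]
    withr::with_seed(100 + seed, {
      x <- rnorm(5); r <- rnorm(5)
    })
    res <- attribute_network(net, x, r, 1L)
    expect_equal(as.vector(res$scores), w_eff * (x - r), tolerance = 1e-10)
  }
})

test_that("explaining a sample against itself gives all-zero scores", {
  net <- random_net(3)
  withr::with_seed(5, x <- matrix(rnorm(12), 2, 6))
  res <- attribute_network(net, x, x[1, ], 1L)
  expect_equal(res$scores[1, ], rep(0, 6), ignore_attr = TRUE)
  expect_equal(res$delta_o[1], 0)
})

test_that("summation-to-delta holds on random nonlinear networks", {
  for (seed in 1:10) {
    net <- random_net(seed)
    withr::with_seed(200 + seed, {
      x <- matrix(rnorm(5 * 6), 5, 6)
      r <- matrix(rnorm(4 * 6), 4, 6)
    })
    for (target in 1:2) {
      res <- attribute_network(net, x, r, target)
      expect_lt(res$max_rel_error, 1e-5)
      # averaged scores sum to f(x) - mean_r f(r)
      expect_equal(rowSums(res$scores), res$delta_o, tolerance = 1e-8)
    }
  }
})

test_that("absolute-mean aggregation ranks by magnitude, not sign", {
  fake <- structure(list(
    scores = matrix(c(-3, 2), 1, dimnames = list(NULL, c("g1", "g2"))),
    delta_o = -1, target = target_spec("class_logit", 1L),
    reference = list(strategy = "custom", k_refs = 1L),
    method = "rescale", max_rel_error = 0), class = "attribution_result")
  rk <- aggregate_abs_mean(fake)
  expect_equal(rk$gene_id, c("g1", "g2"))
  expect_equal(rk$score, c(3, 2))

  # opposite signs across samples must not cancel
  fake$scores <- matrix(c(1, -1, 0.1, 0.1), 2,
                        dimnames = list(NULL, c("g1", "g2")))
  rk2 <- aggregate_abs_mean(fake)
  expect_equal(rk2$score[rk2$gene_id == "g1"], 1)

  # permutation of samples leaves the ranking unchanged
  fake$scores <- fake$scores[2:1, ]
  expect_equal(aggregate_abs_mean(fake), rk2)
  expect_error(aggregate_abs_mean(fake, sample_mask = logical(2)), "no samples")
})

test_that("class explanations on the planted fixture surface planted genes", {
  m <- small_model()
  ds <- small_dataset()
  em <- ds$matrix
  refs <- build_reference_set(em, "random_train", k_refs = 30L, seed = 1L)
  rk <- explain_class_by_genes(m, "C1", em$values[em$class_labels == "C1", ],
                               refs)
  planted <- planted_gene_ids(ds$truth, "C1", em$gene_ids)
  top <- rk$gene_id[seq_along(planted)]
  expect_gte(length(intersect(top, planted)), length(planted) - 3L)
  # a sample explained against itself as reference gets all-zero scores
  row <- which(em$class_labels == "C1")[1]
  res0 <- attribute(m, em$values[row, , drop = FALSE],
                    em$values[row, , drop = FALSE],
                    target_spec("class_logit", "C1", "input_genes"))
  expect_equal(max(abs(res0$scores)), 0)
  expect_equal(res0$delta_o, 0, ignore_attr = TRUE)
  expect_error(explain_class_by_genes(m, "nope", em$values[1:2, ], refs),
               "unknown class")
})

test_that("latent-space class explanation obeys dead paths and completeness", {
  m <- small_model()
  ds <- small_dataset()
  em <- ds$matrix
  refs <- build_reference_set(em, "random_train", k_refs = 20L, seed = 2L)
  # zero the classifier's first-layer weights for one latent dim
  j <- 3L
  m2 <- m
  m2$params$cls[[1]]$W[j, ] <- 0
  rk <- explain_class_by_latent(m2, "C2", em$values[em$class_labels == "C2", ],
                                refs)
  expect_equal(rk$score[rk$gene_id == sprintf("dim_%03d", j)], 0)
  # completeness at the interim layer
  res <- attribute(m, em$values[1:5, ], refs,
                   target_spec("class_logit", "C2", "latent_mu"))
  expect_equal(rowSums(res$scores), res$delta_o, tolerance = 1e-8)
  expect_lt(res$max_rel_error, 1e-5)
})

test_that("latent dimensions are explained by genes with completeness", {
  m <- small_model()
  em <- small_dataset()$matrix
  refs <- build_reference_set(em, "random_train", k_refs = 15L, seed = 3L)
  res <- attribute(m, em$values[1:6, ], refs,
                   target_spec("latent_dim", 2L, "input_genes"))
  expect_equal(rowSums(res$scores), res$delta_o, tolerance = 1e-8)
  # two different dimensions give genuinely different gene rankings
  r1 <- explain_latent_by_genes(m, 1L, em$values[1:40, ], refs)
  r2 <- explain_latent_by_genes(m, 2L, em$values[1:40, ], refs)
  ranks1 <- setNames(r1$rank, r1$gene_id)
  expect_lt(stats::cor(ranks1[r2$gene_id], r2$rank, method = "spearman"), 1)
  expect_error(explain_latent_by_genes(m, 999L, em$values[1:2, ], refs),
               "out of range")
})

test_that("baseline methods match linear closed forms", {
  w <- c(1.5, -2, 0.25)
  net <- mlp_network(dense_layer(matrix(w, 3, 1), b = 1))
  tgt <- target_spec("class_logit", 1L)
  withr::with_seed(9, {
    x <- matrix(rnorm(9), 3, 3)
    r <- matrix(rnorm(15), 5, 3)
  })
  sal <- baseline_attribution("saliency", net, x, target = tgt)
  expect_equal(sal$scores, matrix(abs(w), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  ixg <- baseline_attribution("input_x_gradient", net, x, target = tgt)
  expect_equal(ixg$scores, x * matrix(w, 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  # expected gradients converge to w * (x - mean r) for linear f
  gs <- baseline_attribution("gradient_shap", net, x, r, tgt,
                             n_draws = 10000L, seed = 1L)
  want <- sweep(x, 2, colMeans(r)) * matrix(w, 3, 3, byrow = TRUE)
  expect_equal(gs$scores, want, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("saturated units silence gradients but not rescale attributions", {
  # unit is far past the ReLU hinge for the explained sample, active for the
  # reference: the gradient vanishes while the chord slope does not
  net <- mlp_network(dense_layer(matrix(c(-2, 0), 2, 1), b = 1),
                     activation_layer("relu"),
                     dense_layer(matrix(1, 1, 1)))
  x <- c(5, 0)    # pre-activation 1 - 10 < 0: saturated
  r <- c(0, 0)    # pre-activation 1 > 0: active
  tgt <- target_spec("class_logit", 1L)
  sal <- baseline_attribution("saliency", net, x, target = tgt)
  expect_equal(as.vector(sal$scores), c(0, 0))
  res <- attribute_network(net, x, r, 1L)
  expect_lt(res$scores[1, 1], 0)   # nonzero, and it explains the full delta
  expect_equal(sum(res$scores), res$delta_o)
})

test_that("reference sets are seeded, filtered and validated", {
  em <- small_dataset()$matrix
  a <- build_reference_set(em, "random_train", k_refs = 10L, seed = 4L)
  b <- build_reference_set(em, "random_train", k_refs = 10L, seed = 4L)
  expect_identical(a$profiles, b$profiles)
  fem <- build_reference_set(em, "phenotype_matched", k_refs = 10L,
                             phenotype_filter = c(sex = "female"), seed = 1L)
  expect_true(all(em$phenotypes$sex[match(fem$sample_ids, em$sample_ids)] ==
                    "female"))
  cls <- build_reference_set(em, "phenotype_matched", k_refs = 5L,
                             phenotype_filter = c(class = "C1"), seed = 1L)
  expect_true(all(em$class_labels[match(cls$sample_ids, em$sample_ids)] ==
                    "C1"))
  expect_error(build_reference_set(em, "phenotype_matched", k_refs = 5L,
                                   phenotype_filter = c(sex = "unknown")),
               "no samples")
  expect_error(target_spec("latent_dim", 1L, "latent_mu"), "cannot")
})

test_that("random and phenotype-matched references give related but distinct rankings", {
  m <- small_model()
  ds <- small_dataset()
  em <- ds$matrix
  rows <- em$class_labels == "C1"
  rnd <- build_reference_set(em, "random_train", k_refs = 30L, seed = 6L)
  mat <- build_reference_set(em, "phenotype_matched", k_refs = 30L,
                             phenotype_filter = c(class = "C2"), seed = 6L)
  top <- function(refs) {
    utils::head(explain_class_by_genes(m, "C1", em$values[rows, ], refs)$gene_id,
                30L)
  }
  ja <- overlap_count(top(rnd), top(mat))$jaccard
  expect_gt(ja, 0)
  expect_lt(ja, 1)
})
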