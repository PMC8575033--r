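# Loss functions, the reparameterization trick, training behaviour and the
# deterministic prediction path.

test_that("reparameterization is mu + sigma * eps elementwise", {
  expect_equal(reparameterize(0, 1, 0), 0)
  expect_equal(reparameterize(c(1, 2), c(0.5, 1), c(2, -1)), c(2, 1))
  expect_error(reparameterize(c(1, 2), 1, c(0, 0)), "equal length")
  expect_error(reparameterize(0, -1, 0), "positive")
  # CLT: the sample mean of z concentrates on mu
  withr::with_seed(1, {
    z <- reparameterize(rep(0.7, 1e5), rep(2, 1e5), rnorm(1e5))
  })
  expect_lt(abs(mean(z) - 0.7), 3 * 2 / sqrt(1e5))
})

test_that("KL closed form matches known values and numerical integration", {
  expect_equal(kl_unit_gaussian(0, 1), 0)
  expect_equal(kl_unit_gaussian(1, 1), 0.5)
  expect_error(kl_unit_gaussian(0, 0), "positive")
  # independent oracle: quadrature of q * log(q/p) per dimension
  kl_quad <- function(mu, sigma) {
    stats::integrate(function(x) {
      q <- stats::dnorm(x, mu, sigma)
      ifelse(q > 0, q * (stats::dnorm(x, mu, sigma, log = TRUE) -
                           stats::dnorm(x, log = TRUE)), 0)
    }, -Inf, Inf)$value
  }
  withr::with_seed(4, {
    for (i in 1:10) {
      mu <- rnorm(3); sigma <- runif(3, 0.3, 2.5)
      expect_equal(kl_unit_gaussian(mu, sigma),
                   sum(mapply(kl_quad, mu, sigma)), tolerance = 1e-6)
    }
  })
})

test_that("the negative ELBO decomposes into reconstruction and KL terms", {
  g <- 40L
  x <- matrix(0.5, 2, g)
  # BCE at p = 0.5 is exactly g * ln 2; KL at (0, 1) is 0
  expect_equal(vae_loss(x, x, mu = matrix(0, 2, 3),
                        sigma = matrix(1, 2, 3)), g * log(2))
  # reconstruction weight 0 isolates the KL term
  withr::with_seed(2, {
    mu <- matrix(rnorm(6), 2); sigma <- matrix(runif(6, 0.5, 2), 2)
  })
  expect_equal(vae_loss(x, x, mu, sigma, recon_weight = 0),
               mean(c(kl_unit_gaussian(mu[1, ], sigma[1, ]),
                      kl_unit_gaussian(mu[2, ], sigma[2, ]))))
  expect_error(vae_loss(x + 2, x, mu, sigma), "\\[0, 1\\]")
})

test_that("classification loss matches softmax closed forms", {
  # uniform logits over C classes -> ln C
  expect_equal(classification_loss(matrix(0, 1, 5), 3L), log(5))
  # 3-class toy: logits (2,0,0), true class 1
  expect_equal(classification_loss(matrix(c(2, 0, 0), 1), 1L),
               -log(exp(2) / (exp(2) + 2)))
  # loss vanishes as the correct-class margin grows
  expect_lt(classification_loss(matrix(c(50, 0, 0), 1), 1L), 1e-20)
  expect_error(classification_loss(matrix(0, 1, 3), "D",
                                   classes = c("A", "B", "C")), "vocabulary")
})

test_that("total loss is the weighted combination", {
  expect_equal(total_loss(4, 1, 1, 0), 4)
  expect_equal(total_loss(4, 1, 0, 1), 1)
  expect_equal(total_loss(4, 1, 0.5, 2), 4)
  expect_error(total_loss(1, 1, -1, 0))
})

test_that("training reduces the loss and is reproducible from the seed", {
  ds <- generate_dataset(synthetic_spec(n_samples = 200L, n_genes = 100L,
                                        n_classes = 2L, planted_per_class = 8L,
                                        na_rate = 0, seed = 31L))
  h <- vae_hyperparams(latent_dim = 4L, encoder_hidden = 32L,
                       epochs_unsupervised = 5L, epochs_supervised = 0L,
                       seed = 1L)
  m1 <- train_vae_classifier(ds$matrix, h)
  tot <- m1$history$total
  expect_gte(sum(diff(tot) < 0), 4L)       # monotone in >= 4 of 5 transitions
  m2 <- train_vae_classifier(ds$matrix, h)
  expect_identical(m1$history$total[1], m2$history$total[1])
  expect_identical(m1$params$enc[[1]]$W, m2$params$enc[[1]]$W)
})

test_that("prediction reads mu only and normalizes probabilities", {
  m <- small_model()
  ds <- small_dataset()
  x <- ds$matrix$values[1:7, ]
  p <- predict(m, x)
  expect_equal(unname(rowSums(p$probabilities)), rep(1, 7), tolerance = 1e-6)
  expect_identical(max.col(p$probabilities), max.col(p$logits))
  # perturbing the sigma head must not change predictions
  m2 <- m
  m2$params$lv$W <- m2$params$lv$W + 5
  m2$params$lv$b <- m2$params$lv$b - 3
  p2 <- predict(m2, x)
  expect_identical(p$logits, p2$logits)
  # repeated calls are bitwise identical (no sampling on the predict path)
  expect_identical(predict(m, x)$logits, p$logits)
  expect_error(predict(m, x[, 1:10]), "expects")
})

test_that("a model trained with beta = 0 classifies at chance", {
  ds <- generate_dataset(synthetic_spec(n_samples = 160L, n_genes = 80L,
                                        n_classes = 2L, planted_per_class = 6L,
                                        na_rate = 0, seed = 13L))
  h <- vae_hyperparams(latent_dim = 4L, encoder_hidden = 32L,
                       epochs_unsupervised = 3L, epochs_supervised = 10L,
                       beta = 0, seed = 2L)
  # beta = 0 disables the supervised phase entirely: the head stays random
  m <- train_vae_classifier(ds$matrix, h)
  acc <- classification_accuracy(m, ds$matrix)
  expect_lt(abs(acc - 0.5), 0.2)
})

test_that("the supervised model separates planted classes well above baseline", {
  m <- small_model()
  ds <- small_dataset()
  acc <- classification_accuracy(m, ds$matrix)
  majority <- max(table(ds$matrix$class_labels)) / n_samples(ds$matrix)
  expect_gte(acc - majority, 0.5)
})

test_that("stratified splits keep class proportions and partition samples", {
  labels <- factor(rep(c("A", "B", "C"), times = c(50, 30, 20)))
  sp <- stratified_split(labels, 0.2, seed = 3L)
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_equal(as.vector(table(labels[sp$test])), c(10, 6, 4))
})

test_that("models survive a save/load round trip", {
  m <- small_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  x <- small_dataset()$matrix$values[1:3, ]
  expect_identical(predict(m, x)$logits, predict(m2, x)$logits)
})

test_that("incomplete or out-of-range matrices refuse to train", {
  v <- matrix(c(0.5, NA, 0.2, 0.4), 2, 2)
  em <- expression_matrix(v, class_labels = c("a", "b"))
  expect_error(train_vae_classifier(em), "missing")
  em2 <- expression_matrix(matrix(c(0.5, 3, 0.2, 0.4), 2, 2),
                           class_labels = c("a", "b"))
  expect_error(train_vae_classifier(em2), "\\[0, 1\\]")
})
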