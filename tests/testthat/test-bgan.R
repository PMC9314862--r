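test_that("leaky ReLU follows its two branches", {
  expect_equal(leaky_relu(3, 0.01), 3)
  expect_equal(leaky_relu(-2, 0.01), -0.02)
  expect_equal(leaky_relu(0, 0.5), 0)
  expect_equal(leaky_relu(c(-1, 1), 0.1), c(-0.1, 1))
})

test_that("binary cross-entropy matches closed forms and stays finite", {
  expect_equal(bce_loss(1 - 1e-7, 1), 1e-7, tolerance = 1e-6)
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0)), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 1), -log(1e-7), tolerance = 1e-6)
  expect_true(is.finite(bce_loss(c(0, 1), c(1, 0))))
  expect_error(bce_loss(c(0.5, 0.5), 1), "length")
})

test_that("network shapes follow the spec algebra", {
  spec <- bgan_spec(1207 + 984, latent_dim = 100)
  expect_equal(spec$encoder_dims[1], 2191L)
  expect_equal(spec$encoder_dims[4], 100L)
  expect_equal(spec$generator_dims, rev(spec$encoder_dims))
  expect_equal(spec$discriminator_dims[1], 2291L)
  # D input width = encoder input + latent for arbitrary valid specs
  for (nf in c(10L, 57L, 300L)) for (lat in c(2L, 8L)) {
    s <- bgan_spec(nf, lat)
    expect_equal(s$discriminator_dims[1], nf + lat)
  }
  expect_error(bgan_spec(10, 4, hidden_dims = c(5, 0)), "hidden")
})

test_that("initialisation and the forward pass are deterministic and shaped", {
  spec <- bgan_spec(12, 4, hidden_dims = c(8, 6))
  m1 <- build_networks(spec, seed = 3)
  m2 <- build_networks(spec, seed = 3)
  expect_identical(m1$E, m2$E)
  expect_identical(m1$D, m2$D)
  z <- matrix(rnorm(5 * 4), 5, 4)
  g <- bganmda:::mlp_forward(m1$G, z, 0.01, 0, FALSE, "linear")$out
  expect_equal(dim(g), c(5L, 12L))
  e <- bganmda:::mlp_forward(m1$E, g, 0.01, 0, FALSE, "linear")$out
  expect_equal(dim(e), c(5L, 4L))
})

test_that("backpropagation gradients match finite differences", {
  set.seed(5)
  net <- bganmda:::mlp_init(c(4, 3, 3, 1))
  x <- matrix(rnorm(8), 2, 4)
  y <- c(1, 0)
  loss_of <- function(net) {
    p <- as.numeric(bganmda:::mlp_forward(net, x, 0.01, 0, FALSE,
                                          "sigmoid")$out)
    bce_loss(p, y)
  }
  fwd <- bganmda:::mlp_forward(net, x, 0.01, 0, TRUE, "sigmoid")
  p <- as.numeric(fwd$out)
  gr <- bganmda:::mlp_backward(net, fwd, matrix((p - y) / 2, ncol = 1), 0.01)
  eps <- 1e-6
  for (l in 1:3) for (idx in list(c(1, 1), c(2, 1))) {
    n2 <- net; n2[[l]]$W[idx[1], idx[2]] <- n2[[l]]$W[idx[1], idx[2]] + eps
    n3 <- net; n3[[l]]$W[idx[1], idx[2]] <- n3[[l]]$W[idx[1], idx[2]] - eps
    num <- (loss_of(n2) - loss_of(n3)) / (2 * eps)
    expect_equal(gr$gW[[l]][idx[1], idx[2]], num, tolerance = 1e-4,
                 info = paste("layer", l))
  }
})

test_that("training is reproducible, improves the discriminator and respects epochs = 0", {
  dat <- small_dataset()
  sims <- similarity_pipeline(dat$assoc, dat$seqs, dat$forest)
  feats <- build_pair_features(sims$ms, sims$ds, dat$assoc)
  spec <- bgan_spec(ncol(feats$x), 4, c(16, 8))
  cfg <- fast_params(epochs = 80)
  m0 <- build_networks(spec, seed = 2)
  expect_identical(bgan_train(m0, feats, fast_params(epochs = 0)), m0)
  t1 <- bgan_train(m0, feats, cfg)
  t2 <- bgan_train(m0, feats, cfg)
  expect_identical(t1$loss, t2$loss)
  expect_identical(bgan_score(t1, feats)$score, bgan_score(t2, feats)$score)
  # discriminator learned: final loss below the initial one
  expect_lt(t1$loss[[1]][80, "d_loss"], t1$loss[[1]][1, "d_loss"])
  expect_true(all(is.finite(unlist(t1$loss))))
})

test_that("training refuses degenerate input and mismatched shapes", {
  feats <- structure(list(x = matrix(0.5, 3, 10), label = c(0, 0, 0),
                          mirna = letters[1:3], disease = letters[4:6],
                          nm = 5, nd = 5), class = "pair_features")
  m <- build_networks(bgan_spec(10, 4, c(8, 6)), 1)
  expect_error(bgan_train(m, feats, fast_params()), "no positive")
  m2 <- build_networks(bgan_spec(12, 4, c(8, 6)), 1)
  feats$label <- c(1, 1, 0)
  expect_error(bgan_train(m2, feats, fast_params()), "does not match")
})

test_that("after training the discriminator separates encoder pairs from generator pairs", {
  dat <- small_dataset()
  sims <- similarity_pipeline(dat$assoc, dat$seqs, dat$forest)
  feats <- build_pair_features(sims$ms, sims$ds, dat$assoc)
  spec <- bgan_spec(ncol(feats$x), 4, c(16, 8))
  m <- bgan_train(build_networks(spec, 2), feats, fast_params(epochs = 150))
  x <- feats$x[feats$label == 1, ]
  rep1 <- m$reps[[1]]
  e <- bganmda:::mlp_forward(rep1$E, x, 0.01, 0, FALSE, "linear")$out
  d_real <- bganmda:::mlp_forward(rep1$D, cbind(x, e), 0.01, 0, FALSE,
                                  "sigmoid")$out
  set.seed(9)
  z <- matrix(rnorm(nrow(x) * 4), nrow(x), 4)
  g <- bganmda:::mlp_forward(rep1$G, z, 0.01, 0, FALSE, "linear")$out
  d_fake <- bganmda:::mlp_forward(rep1$D, cbind(g, z), 0.01, 0, FALSE,
                                  "sigmoid")$out
  expect_gt(mean(d_real), mean(d_fake))
})

test_that("scores are probabilities, deterministic, and stable across save/load", {
  dat <- small_dataset()
  sims <- similarity_pipeline(dat$assoc, dat$seqs, dat$forest)
  feats <- build_pair_features(sims$ms, sims$ds, dat$assoc)
  spec <- bgan_spec(ncol(feats$x), 4, c(16, 8))
  m <- bgan_train(build_networks(spec, 2), feats, fast_params(epochs = 60))
  s <- bgan_score(m, feats)
  expect_true(all(s$score > 0 & s$score < 1))
  # identical feature vectors give identical scores
  x2 <- feats$x[c(1, 1), ]
  expect_equal(diff(bgan_score(m, x2)), 0)
  path <- withr::local_tempfile(fileext = ".rds")
  write_bgan(m, path)
  expect_true(file.exists(paste0(path, ".json")))
  m2 <- read_bgan(path)
  expect_identical(bgan_score(m2, feats)$score, s$score)
})

test_that("the fitted-model front end exposes the standard S3 surface", {
  dat <- small_dataset()
  fit <- bganmda(dat, params = fast_params(epochs = 60))
  expect_s3_class(fit, "bganmda")
  expect_output(print(fit), "adversarial")
  sm <- summary(fit)
  expect_equal(sm$feature_length, 16 + 12)
  expect_equal(sm$discriminator_input, 16 + 12 + 4)
  sc <- predict(fit)
  expect_equal(nrow(sc), 16 * 12)
  expect_true(all(sc$score > 0 & sc$score < 1))
  one <- predict(fit, newdata = data.frame(mirna = "syn-mir-001",
                                           disease = "synthetic disease 001"))
  expect_equal(nrow(one), 1)
  expect_equal(one$score, sc$score[sc$mirna == "syn-mir-001" &
                                     sc$disease == "synthetic disease 001"])
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(3L, 28L))
})
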