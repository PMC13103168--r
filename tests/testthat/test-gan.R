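# GAN construction, initialisation statistics, shape contracts, training
# determinism and boundary behaviour. Heavy end-to-end behaviour lives in
# the acceptance suite; everything here runs on micro-configurations.

test_that("configuration validation catches unsupported geometries", {
  expect_error(gan_config(resolution = 48), "resolution")
  expect_error(gan_config(resolution = 8), "resolution")
  expect_error(gan_config(learning_rate = 0), "learning_rate")
  expect_error(gan_config(beta1 = 1), "beta1")
  expect_error(gan_config(batch_size = 0), "batch_size")
})

test_that("generator and discriminator honour their shape contracts", {
  m <- tiny_gan()
  s <- gan_generate(m, rnorm(8))
  expect_s3_class(s, "image_sample")
  expect_identical(dim(s$pixels), c(16L, 16L))
  expect_true(all(s$pixels > -1 & s$pixels < 1))  # open Tanh range
  p <- gan_discriminate(m, matrix(0, 16, 16))
  expect_length(p, 1)
  expect_true(p > 0 && p < 1)  # sigmoid codomain
  expect_error(gan_generate(m, rnorm(5)), "length 8")
})

test_that("weight initialisation follows the Normal(0, 0.02) scheme", {
  cfg <- gan_config(latent_dim = 64L, resolution = 32L,
                    base_feature_maps = 24L, seed = 1L)
  m <- build_gan(cfg)
  conv_w <- unlist(lapply(m$discriminator$par[grepl(
    "_W$", names(m$discriminator$par))], as.vector))
  n <- length(conv_w)
  expect_gt(n, 5e4)
  expect_lt(abs(mean(conv_w)), 3 * 0.02 / sqrt(n))     # within 3 SE of 0
  expect_lt(abs(sd(conv_w) - 0.02) / 0.02, 0.1)        # std within 10%
  bn_scales <- m$generator$par$bn1_g
  expect_lt(abs(mean(bn_scales) - 1), 0.02)
  expect_true(all(m$generator$par$bn1_b == 0))         # shifts exactly 0
  expect_true(all(m$discriminator$par$conv1_b == 0))
})

test_that("builds and generation are bitwise deterministic given seeds", {
  m1 <- tiny_gan(seed = 5)
  m2 <- tiny_gan(seed = 5)
  expect_identical(m1$generator$par, m2$generator$par)
  expect_identical(m1$discriminator$par, m2$discriminator$par)
  z <- rnorm(8)
  expect_identical(gan_generate(m1, z)$pixels, gan_generate(m1, z)$pixels)
  m3 <- tiny_gan(seed = 6)
  expect_false(identical(m1$generator$par, m3$generator$par))
})

test_that("generator output responds continuously to latent perturbations", {
  m <- tiny_gan()
  z <- rnorm(8)
  base <- gan_generate(m, z)$pixels
  z2 <- z
  z2[3] <- z2[3] + 1e-6
  expect_lt(max(abs(gan_generate(m, z2)$pixels - base)), 1e-3)
  expect_gt(max(abs(gan_generate(m, z2)$pixels - base)), 0)
})

test_that("zero training steps return the input models untouched", {
  cfg <- gan_config(latent_dim = 8L, resolution = 16L, base_feature_maps = 4L,
                    train_steps = 0L, batch_size = 4L, seed = 3L)
  m <- build_gan(cfg)
  train <- generate_dataset(4, 0, phantom_spec("FRONTAL", 16), seed = 2)
  fit <- train_gan(m, train, cfg)
  expect_identical(fit$models$generator$par, m$generator$par)
  expect_identical(fit$models$discriminator$par, m$discriminator$par)
  expect_identical(nrow(fit$trace$losses), 0L)
})

test_that("short training runs are finite, reproducible, and logged", {
  cfg <- gan_config(latent_dim = 8L, resolution = 16L, base_feature_maps = 4L,
                    train_steps = 5L, batch_size = 4L, seed = 3L)
  train <- generate_dataset(8, 0, phantom_spec("FRONTAL", 16), seed = 2)
  fit1 <- train_gan(build_gan(cfg), train, cfg)
  expect_identical(nrow(fit1$trace$losses), 5L)
  expect_true(all(is.finite(fit1$trace$losses$d_loss)))
  expect_true(all(is.finite(fit1$trace$losses$g_loss)))
  expect_identical(fit1$models$trained_steps, 5L)
  fit2 <- train_gan(build_gan(cfg), train, cfg)
  expect_identical(fit1$models$generator$par, fit2$models$generator$par)
  expect_identical(fit1$trace$losses, fit2$trace$losses)
  # monitor latents are a fixed seeded probe batch
  expect_identical(fit1$trace$monitor_latents, fit2$trace$monitor_latents)
})

test_that("training validates its inputs", {
  cfg <- gan_config(latent_dim = 8L, resolution = 16L, base_feature_maps = 4L,
                    train_steps = 1L, batch_size = 4L, seed = 3L)
  m <- build_gan(cfg)
  expect_error(train_gan(m, list(), cfg), "empty")
  wrong <- generate_dataset(4, 0, phantom_spec("FRONTAL", 32), seed = 2)
  expect_error(train_gan(m, wrong, cfg), "resolution")
})

test_that("checkpoints round-trip through save_gan/load_gan", {
  d <- withr::local_tempdir()
  m <- tiny_gan(steps = 2)
  f <- file.path(d, "ck.rds")
  save_gan(m, f)
  m2 <- load_gan(f)
  expect_identical(m2$generator$par, m$generator$par)
  expect_identical(m2$trained_steps, 2L)
  saveRDS(1:3, f)
  expect_error(load_gan(f), "checkpoint")
})

test_that("glance() summarises a model and autoplot renders a trace", {
  cfg <- gan_config(latent_dim = 8L, resolution = 16L, base_feature_maps = 4L,
                    train_steps = 3L, batch_size = 4L, seed = 3L)
  train <- generate_dataset(6, 0, phantom_spec("FRONTAL", 16), seed = 2)
  fit <- train_gan(build_gan(cfg), train, cfg)
  gl <- glance(fit$models)
  expect_identical(gl$trained_steps, 3L)
  expect_gt(gl$n_params_generator, 0)
  expect_s3_class(autoplot(fit$trace), "ggplot")
  expect_s3_class(autoplot(gan_generate(fit$models, rnorm(8))), "ggplot")
})
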