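# Latent-space inversion and the OOD decision rule, on micro-models.

test_that("inversion config validates its invariants", {
  expect_error(inversion_config(loss_threshold = 0), "loss_threshold")
  expect_error(inversion_config(alpha = 0), "alpha")
  expect_error(inversion_config(extra_steps = 50, max_steps = 20),
               "max_steps")
  expect_error(inversion_config(restarts = 0), "restarts")
})

test_that("reconstruction loss matches an elementwise oracle", {
  m <- tiny_gan()
  set.seed(6)
  z <- rnorm(8)
  x <- generate_phantom(phantom_spec("FRONTAL", 16, 0.1, 0.2, 4))$pixels
  # independent arithmetic: explicit per-pixel loop
  g <- gan_generate(m, z)$pixels
  acc <- 0
  for (i in seq_len(16)) for (j in seq_len(16)) acc <- acc + (g[i, j] - x[i, j])^2
  expect_equal(reconstruction_loss(m, z, x), acc / 256)
  # identity: zero loss iff the target is the generator output itself
  expect_equal(reconstruction_loss(m, z, g), 0)
  expect_error(reconstruction_loss(m, z, matrix(0, 8, 8)), "resolution")
})

test_that("budget exhaustion stops after max_steps without reaching tau", {
  m <- tiny_gan()
  x <- generate_phantom(phantom_spec("LATERAL", 16, 0, 0.2, 9))$pixels
  r <- invert_image(m, x, inversion_config(loss_threshold = 1e-9,
                                           extra_steps = 0, max_steps = 1))
  expect_false(r$reached_threshold)
  expect_identical(r$total_steps, 1L)
  expect_identical(r$steps_to_threshold, NA_integer_)
  expect_length(r$loss_trace, 1)
})

test_that("the stopping rule honours tau and extra refinement steps", {
  m <- tiny_gan()
  x <- generate_phantom(phantom_spec("FRONTAL", 16, 0, 0.2, 9))$pixels
  # a loose tau is hit at step 1; exactly extra_steps more updates follow
  r <- invert_image(m, x, inversion_config(loss_threshold = 100,
                                           extra_steps = 7, max_steps = 50))
  expect_true(r$reached_threshold)
  expect_identical(r$steps_to_threshold, 1L)
  expect_identical(r$total_steps, 8L)
  expect_lte(r$loss_trace[r$steps_to_threshold], 100)
  expect_true(all(is.finite(r$loss_trace)))
})

test_that("inversion is deterministic and restarts keep the best run", {
  m <- tiny_gan(steps = 10)
  x <- generate_phantom(phantom_spec("FRONTAL", 16, 0, 0.2, 9))$pixels
  cfg <- inversion_config(loss_threshold = 1e-6, extra_steps = 5,
                          max_steps = 40, z_seed = 2)
  r1 <- invert_image(m, x, cfg)
  r2 <- invert_image(m, x, cfg)
  expect_identical(r1$loss_trace, r2$loss_trace)
  expect_identical(r1$z_final, r2$z_final)
  cfg3 <- cfg
  cfg3$restarts <- 3L
  r3 <- invert_image(m, x, cfg3)
  expect_lte(r3$final_loss, r1$final_loss)
})

test_that("detection composes inversion with the KS decision", {
  m <- tiny_gan(steps = 10)
  x <- generate_phantom(phantom_spec("FRONTAL", 16, 0, 0.2, 9))$pixels
  # threshold unreachable in one step: OOD via the failure route
  d1 <- detect_ood(m, x, inversion_config(loss_threshold = 1e-9,
                                          extra_steps = 0, max_steps = 1))
  expect_true(d1$is_ood)
  expect_identical(d1$failure_mode, "THRESHOLD_NOT_REACHED")
  expect_s3_class(d1$ks, "ks_test_result")  # KS still reported
  # alpha ~ 1 with a reachable threshold: flagged OOD since p < 1
  d2 <- detect_ood(m, x, inversion_config(loss_threshold = 100,
                                          extra_steps = 0, max_steps = 5,
                                          alpha = 1 - 1e-9))
  expect_identical(d2$failure_mode, "NONE")
  expect_true(d2$is_ood)
  expect_identical(tidy(d2)$p.value, d2$ks$p_value)
})

test_that("the ID call is monotone in the significance level", {
  m <- tiny_gan(steps = 10)
  set.seed(8)
  x <- gan_generate(m, rnorm(8))$pixels
  cfg <- inversion_config(loss_threshold = 100, extra_steps = 10,
                          max_steps = 20, z_seed = 3)
  ds <- lapply(c(1e-6, 0.05, 0.5), function(a) {
    cfg$alpha <- a
    detect_ood(m, x, cfg)
  })
  # same trace, shrinking alpha: once ID, stays ID at every smaller alpha
  expect_identical(ds[[1]]$ks$d_statistic, ds[[2]]$ks$d_statistic)
  if (!ds[[3]]$is_ood) expect_false(ds[[2]]$is_ood || ds[[1]]$is_ood)
  if (!ds[[2]]$is_ood) expect_false(ds[[1]]$is_ood)
})

test_that("dataset detection returns one tidy row per image", {
  m <- tiny_gan(steps = 10)
  ds <- generate_dataset(2, 2, phantom_spec("FRONTAL", 16), seed = 31)
  det <- detect_dataset(m, ds, inversion_config(loss_threshold = 0.05,
                                                extra_steps = 5,
                                                max_steps = 15))
  expect_identical(nrow(det), 4L)
  expect_named(det, c("id", "label", "is_ood", "p_value", "d_statistic",
                      "loss", "steps", "failure_mode"))
  expect_true(all(det$failure_mode %in% c("NONE", "THRESHOLD_NOT_REACHED")))
  expect_true(all(det$loss >= 0))
})

test_that("sweeping thresholds reproduces per-tau detect decisions exactly", {
  # the cached-trajectory sweep must agree with running detect_ood per tau
  m <- tiny_gan(steps = 10)
  ds <- generate_dataset(3, 3, phantom_spec("FRONTAL", 16), seed = 77)
  base <- inversion_config(loss_threshold = 0.05, extra_steps = 5,
                           max_steps = 15, z_seed = 1)
  taus <- c(0.01, 0.2, 5)
  sw <- sweep_detector(m, ds, taus, extra_steps = 5, base_config = base)
  for (k in seq_along(taus)) {
    pred <- vapply(seq_len(nrow(ds)), function(i) {
      cfg_i <- base
      cfg_i$loss_threshold <- taus[k]
      cfg_i$z_seed <- latentks:::derive_seed(base$z_seed, i)
      detect_ood(m, ds$pixels[[i]], cfg_i)$is_ood
    }, logical(1))
    truth <- ds$label != "FRONTAL"
    mr <- metrics_from_confusion(confusion_matrix(truth, pred))
    expect_equal(sw$accuracy[k], mr$accuracy)
    expect_equal(sw$f1[k], mr$f1)
  }
})
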