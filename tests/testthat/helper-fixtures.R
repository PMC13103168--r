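# Shared fixtures. The trained GAN used by the end-to-end tests is expensive
# (999 steps at 64x64), so it is trained once per test run and cached, along
# with the held-out evaluation set and the threshold sweep computed from it.

fixture_cache <- new.env(parent = emptyenv())

# Desk-scale study conditions: 200 frontal phantoms at the phantom defaults
# (noise 0.01, jitter 0.2), compact GAN width 12, batch 16, 999 steps.
fixture_train_config <- function() {
  gan_config(latent_dim = 100L, resolution = 64L, base_feature_maps = 12L,
             train_steps = 999L, batch_size = 16L, seed = 0L)
}

fixture_detect_config <- function(z_seed = 5L) {
  inversion_config(loss_threshold = 0.15, extra_steps = 200L,
                   max_steps = 400L, z_seed = z_seed, restarts = 3L)
}

fixture_gan <- function() {
  if (is.null(fixture_cache$models)) {
    cfg <- fixture_train_config()
    train <- generate_dataset(200, 0, phantom_spec("FRONTAL", 64), seed = 11)
    fixture_cache$models <- train_gan(build_gan(cfg), train, cfg)$models
  }
  fixture_cache$models
}

fixture_test_set <- function() {
  if (is.null(fixture_cache$test_set)) {
    fixture_cache$test_set <-
      generate_dataset(20, 20, phantom_spec("FRONTAL", 64), seed = 999)
  }
  fixture_cache$test_set
}

fixture_sweep <- function() {
  if (is.null(fixture_cache$sweep)) {
    fixture_cache$sweep <- sweep_detector(
      fixture_gan(), fixture_test_set(),
      taus = c(0.02, 0.05, 0.1, 0.15, 0.2),
      extra_steps = 200L, base_config = fixture_detect_config())
  }
  fixture_cache$sweep
}

# A throwaway micro-GAN (16x16, width 4) for unit tests of the network
# machinery; untrained unless steps > 0.
tiny_gan <- function(steps = 0L, seed = 3L) {
  cfg <- gan_config(latent_dim = 8L, resolution = 16L, base_feature_maps = 4L,
                    train_steps = as.integer(steps), batch_size = 4L,
                    seed = seed)
  models <- build_gan(cfg)
  if (steps > 0) {
    train <- generate_dataset(12, 0, phantom_spec("FRONTAL", 16), seed = 2)
    models <- train_gan(models, train, cfg)$models
  }
  models
}
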