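#' Configure latent-space inversion and the OOD decision rule
#'
#' The detector reconstructs a target image by optimizing a latent vector z
#' (generator frozen, inference mode) to minimise the mean squared pixel
#' difference between G(z) and the target. Optimisation stops when the loss
#' first reaches `loss_threshold` (tau), after which `extra_steps` further
#' refinement updates are run; if tau is never reached within `max_steps`
#' the image is flagged out-of-distribution outright. Once stopped, a
#' two-sample Kolmogorov-Smirnov test compares the pixel-value distributions
#' of the reconstruction and the target, and the image is called OOD when the
#' p-value falls below `alpha`.
#'
#' The loss is the mean (not the sum) of squared pixel differences on the
#' \[-1, 1\] scale, so tau values like 0.15-0.4 are resolution-independent
#' and commensurate with published threshold sweeps.
#'
#' @param learning_rate Adam learning rate for z (default 0.001).
#' @param loss_threshold Convergence threshold tau on the mean squared error.
#' @param extra_steps Refinement updates after tau is first reached.
#' @param max_steps Optimisation budget cap (must be >= `extra_steps`).
#' @param alpha Significance level of the KS decision (default 0.05).
#' @param z_seed Seed for the standard-Normal initialisation of z.
#' @param restarts Independent restarts; the run with the lowest final loss
#'   wins (inversion is non-convex).
#' @return An object of class `inversion_config`.
#' @export
inversion_config <- function(learning_rate = 0.001, loss_threshold = 0.15,
                             extra_steps = 95L, max_steps = 300L,
                             alpha = 0.05, z_seed = 0L, restarts = 1L) {
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(loss_threshold, "loss_threshold", lower = 1e-12)
  check_number(extra_steps, "extra_steps", lower = 0, integerish = TRUE)
  check_number(max_steps, "max_steps", lower = 1, integerish = TRUE)
  if (max_steps < extra_steps)
    abort_field("max_steps", "must be >= extra_steps")
  check_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_number(z_seed, "z_seed", integerish = TRUE)
  check_number(restarts, "restarts", lower = 1, integerish = TRUE)
  structure(list(learning_rate = learning_rate,
                 loss_threshold = loss_threshold,
                 extra_steps = as.integer(extra_steps),
                 max_steps = as.integer(max_steps), alpha = alpha,
                 z_seed = as.integer(z_seed), restarts = as.integer(restarts)),
            class = "inversion_config")
}

#' Reconstruction loss between G(z) and a target image
#'
#' Mean over pixels of the squared difference between the generator output
#' and the target; non-negative, zero iff the images are identical.
#'
#' @param models A trained [gan_models] object.
#' @param z Latent vector.
#' @param x Target [image_sample()] or pixel matrix.
#' @return A single non-negative number.
#' @export
reconstruction_loss <- function(models, z, x) {
  xm <- if (is_image_sample(x)) x$pixels else x
  if (nrow(xm) != models$config$resolution)
    abort_field("x", "resolution does not match the model")
  g <- gan_generate(models, z)
  mean((g$pixels - xm)^2)
}

# Loss and gradient of the mean-squared reconstruction objective at z.
# Generator is evaluated in inference mode so the map z -> G(z) is fixed.
z_loss_grad <- function(models, z, xm) {
  cfg <- models$config
  fw <- g_fwd(models$generator, cfg, matrix(z, ncol = 1), train = FALSE)
  npix <- length(xm)
  diff <- fw$out - matrix(xm, nrow = 1L)  # columns are (h, w) pixel order
  dout <- 2 * diff / npix
  bw <- g_bwd(models$generator, cfg, fw$caches, dout, param_grad = FALSE)
  list(loss = sum(diff * diff) / npix, grad = as.vector(bw$dZ))
}

# One full (un-stopped) optimisation trajectory: Adam on z for max_steps,
# recording the loss before each update and every iterate of z. The stopping
# rule for any (tau, extra_steps) can then be replayed exactly: the iterate
# sequence never depends on tau.
invert_trajectory <- function(models, xm, learning_rate, max_steps, z_seed) {
  latent <- models$config$latent_dim
  z <- with_seed_(z_seed, stats::rnorm(latent))
  Z <- matrix(0, latent, max_steps + 1L)
  Z[, 1L] <- z
  losses <- numeric(max_steps)
  m <- numeric(latent)
  v <- numeric(latent)
  for (t in seq_len(max_steps)) {
    lg <- z_loss_grad(models, z, xm)
    if (!is.finite(lg$loss))
      stop(sprintf("inversion diverged at step %d (non-finite loss)", t),
           call. = FALSE)
    losses[t] <- lg$loss
    m <- 0.9 * m + 0.1 * lg$grad
    v <- 0.999 * v + 0.001 * lg$grad^2
    mh <- m / (1 - 0.9^t)
    vh <- v / (1 - 0.999^t)
    z <- z - learning_rate * mh / (sqrt(vh) + 1e-8)
    Z[, t + 1L] <- z
  }
  list(losses = losses, Z = Z)
}

# Apply the tau/extra_steps stopping rule to a recorded trajectory.
apply_stop_rule <- function(traj, loss_threshold, extra_steps, max_steps) {
  n <- min(length(traj$losses), max_steps)
  reached_at <- which(traj$losses[seq_len(n)] <= loss_threshold)
  if (length(reached_at) > 0L) {
    s <- reached_at[1L]
    total <- min(s + extra_steps, n)
    list(reached = TRUE, s = s, total = total)
  } else {
    list(reached = FALSE, s = NA_integer_, total = n)
  }
}

#' Invert the generator for a target image
#'
#' Initialises z from a standard Normal (seeded by `config$z_seed`), runs
#' Adam on z alone with the generator frozen in inference mode, and applies
#' the threshold-plus-extra-steps stopping rule. With `restarts > 1`,
#' independent restarts are run from derived seeds and the one with the
#' lowest final loss is returned. Deterministic given the seeds.
#'
#' @param models A trained [gan_models] object.
#' @param x Target [image_sample()] or pixel matrix.
#' @param config An [inversion_config()].
#' @return An object of class `inversion_result`: list with `z_final`,
#'   `loss_trace`, `reached_threshold`, `steps_to_threshold`, `total_steps`,
#'   and `final_loss` (loss at `z_final`).
#' @export
invert_image <- function(models, x, config = inversion_config()) {
  xm <- if (is_image_sample(x)) x$pixels else x
  if (nrow(xm) != models$config$resolution)
    abort_field("x", "resolution does not match the model")
  best <- NULL
  for (r in seq_len(config$restarts)) {
    seed_r <- if (r == 1L) config$z_seed else derive_seed(config$z_seed, r)
    traj <- invert_trajectory(models, xm, config$learning_rate,
                              config$max_steps, seed_r)
    stp <- apply_stop_rule(traj, config$loss_threshold, config$extra_steps,
                           config$max_steps)
    z_fin <- traj$Z[, stp$total + 1L]
    fin_loss <- mean((gan_generate(models, z_fin)$pixels - xm)^2)
    res <- structure(list(z_final = z_fin,
                          loss_trace = traj$losses[seq_len(stp$total)],
                          reached_threshold = stp$reached,
                          steps_to_threshold =
                            if (stp$reached) stp$s else NA_integer_,
                          total_steps = stp$total,
                          final_loss = fin_loss),
                     class = "inversion_result")
    if (is.null(best) || fin_loss < best$final_loss) best <- res
  }
  best
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf(paste0("<inversion_result> %d steps, threshold %s",
                     " (at step %s), final loss %.5g\n"),
              x$total_steps,
              if (x$reached_threshold) "reached" else "not reached",
              if (x$reached_threshold) x$steps_to_threshold else "-",
              x$final_loss))
  invisible(x)
}

#' Decide whether an image is out-of-distribution
#'
#' Runs [invert_image()] and then the two-sample KS test between the flattened
#' pixel values of the reconstruction G(z_final) and of the target. The image
#' is flagged OOD when the reconstruction loss never reached the threshold
#' (failure to reconstruct is itself OOD evidence; `failure_mode`
#' `"THRESHOLD_NOT_REACHED"`, KS still reported for diagnostics) or when the
#' KS p-value is below `config$alpha`.
#'
#' @inheritParams invert_image
#' @return An object of class `detection_result`: list with `is_ood`, `ks`
#'   (a `ks_test_result`), `reconstruction_loss`, `failure_mode`, and the
#'   underlying `inversion` result.
#' @export
detect_ood <- function(models, x, config = inversion_config()) {
  xm <- if (is_image_sample(x)) x$pixels else x
  inv <- invert_image(models, xm, config)
  recon <- gan_generate(models, inv$z_final)$pixels
  ks <- ks_two_sample(as.vector(recon), as.vector(xm))
  failure <- if (inv$reached_threshold) "NONE" else "THRESHOLD_NOT_REACHED"
  is_ood <- !inv$reached_threshold || ks$p_value < config$alpha
  structure(list(is_ood = is_ood, ks = ks,
                 reconstruction_loss = inv$final_loss,
                 failure_mode = failure, inversion = inv,
                 alpha = config$alpha),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> %s (D = %.4f, p = %.4g, loss = %.4g%s)\n",
              if (x$is_ood) "OOD" else "ID", x$ks$d_statistic, x$ks$p_value,
              x$reconstruction_loss,
              if (x$failure_mode == "NONE") ""
              else ", threshold not reached"))
  invisible(x)
}

#' Detect over a dataset
#'
#' Applies [detect_ood()] to every row of a dataset tibble, with per-image
#' z seeds derived from `config$z_seed` so results do not depend on row
#' order subsetting.
#'
#' @param models A trained [gan_models] object.
#' @param data Dataset tibble with `pixels` (list-column) and optionally
#'   `label` and `id` columns.
#' @param config An [inversion_config()].
#' @return A tibble with one row per image: `id`, `label`, `is_ood`,
#'   `p_value`, `d_statistic`, `loss`, `steps`, `failure_mode`.
#' @export
detect_dataset <- function(models, data, config = inversion_config()) {
  n <- nrow(data)
  rows <- lapply(seq_len(n), function(i) {
    cfg_i <- config
    cfg_i$z_seed <- derive_seed(config$z_seed, i)
    det <- detect_ood(models, data$pixels[[i]], cfg_i)
    tibble::tibble(id = (data$id %||% seq_len(n))[i],
                   label = (data$label %||% rep("UNKNOWN", n))[i],
                   is_ood = det$is_ood, p_value = det$ks$p_value,
                   d_statistic = det$ks$d_statistic,
                   loss = det$reconstruction_loss,
                   steps = det$inversion$total_steps,
                   failure_mode = det$failure_mode)
  })
  dplyr::bind_rows(rows)
}
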