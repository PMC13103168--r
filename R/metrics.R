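# Evaluation harness: confusion-matrix metrics (OOD is the positive class),
# loss-threshold sweeps, and ANOVA over replicate accuracies.

#' Confusion matrix with OOD as the positive class
#'
#' @param truth_ood,pred_ood Logical vectors of equal length.
#' @return An object of class `confusion_matrix`: list with `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion_matrix <- function(truth_ood, pred_ood) {
  if (length(truth_ood) != length(pred_ood))
    abort_field("pred_ood", "must match truth_ood in length")
  truth_ood <- as.logical(truth_ood)
  pred_ood <- as.logical(pred_ood)
  structure(list(tp = sum(truth_ood & pred_ood),
                 fp = sum(!truth_ood & pred_ood),
                 fn = sum(truth_ood & !pred_ood),
                 tn = sum(!truth_ood & !pred_ood)),
            class = "confusion_matrix")
}

#' Metrics from a confusion matrix
#'
#' Accuracy, precision, recall and F1 with OOD positive. Zero-denominator
#' conventions: precision and recall are 0 when undefined, F1 is 0 when
#' precision + recall is 0. Values are never rounded internally; round only
#' for reporting.
#'
#' @param cm A [confusion_matrix()] (or list with `tp`, `fp`, `fn`, `tn`).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`.
#' @export
metrics_from_confusion <- function(cm) {
  tp <- cm$tp
  fp <- cm$fp
  fn <- cm$fn
  tn <- cm$tn
  total <- tp + fp + fn + tn
  if (total < 1) abort_field("cm", "must contain at least one sample")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  tibble::tibble(accuracy = (tp + tn) / total, precision = precision,
                 recall = recall, f1 = f1_from_pr(precision, recall))
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2PR / (P + R)`, 0 when both are 0.
#'
#' @param precision,recall Values in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_from_pr <- function(precision, recall) {
  check_number(precision, "precision", lower = 0, upper = 1)
  check_number(recall, "recall", lower = 0, upper = 1)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

# Shared machinery for sweeps: one full inversion trajectory per image (and
# restart), after which any (tau, extra_steps) stopping rule can be replayed
# exactly -- the iterate sequence does not depend on tau, so caching cannot
# change results relative to running detect_ood per tau.
sweep_trajectories <- function(models, test_set, base_config) {
  lapply(seq_len(nrow(test_set)), function(i) {
    z0 <- derive_seed(base_config$z_seed, i)
    lapply(seq_len(base_config$restarts), function(r) {
      seed_r <- if (r == 1L) z0 else derive_seed(z0, r)
      invert_trajectory(models, test_set$pixels[[i]],
                        base_config$learning_rate, base_config$max_steps,
                        seed_r)
    })
  })
}

sweep_decide <- function(models, xm, trajs, tau, extra_steps, max_steps,
                         alpha) {
  best <- NULL
  for (traj in trajs) {
    stp <- apply_stop_rule(traj, tau, extra_steps, max_steps)
    z_fin <- traj$Z[, stp$total + 1L]
    recon <- gan_generate(models, z_fin)$pixels
    fin_loss <- mean((recon - xm)^2)
    if (is.null(best) || fin_loss < best$fin_loss)
      best <- list(stp = stp, recon = recon, fin_loss = fin_loss)
  }
  ks <- ks_two_sample(as.vector(best$recon), as.vector(xm))
  list(is_ood = !best$stp$reached || ks$p_value < alpha,
       reached = best$stp$reached, p_value = ks$p_value,
       d = ks$d_statistic, loss = best$fin_loss)
}

#' Sweep the detector over loss thresholds
#'
#' Runs the GAN detector on every test image for each threshold tau in
#' `taus`, and emits one metrics row per tau (OOD positive; an image is OOD
#' when its label differs from `id_label`). Inversion trajectories are
#' computed once per image and the stopping rule is re-applied exactly per
#' tau, which is equivalent to (and much cheaper than) re-running the full
#' optimisation for every threshold.
#'
#' @param models A trained [gan_models] object.
#' @param test_set Dataset tibble with `pixels` and `label`, both classes
#'   present.
#' @param taus Numeric vector of loss thresholds.
#' @param extra_steps Refinement steps after the threshold is reached.
#' @param base_config An [inversion_config()] supplying learning rate, step
#'   budget, alpha, seed and restarts.
#' @param id_label Label of the in-distribution class.
#' @return Tibble with one row per tau: `loss_threshold`, `extra_steps`,
#'   `accuracy`, `precision`, `recall`, `f1`.
#' @export
sweep_detector <- function(models, test_set, taus, extra_steps = 95L,
                           base_config = inversion_config(),
                           id_label = "FRONTAL") {
  if (length(taus) == 0L) {
    return(tibble::tibble(loss_threshold = numeric(), extra_steps = integer(),
                          accuracy = numeric(), precision = numeric(),
                          recall = numeric(), f1 = numeric()))
  }
  truth <- test_set$label != id_label
  if (!any(truth) || all(truth))
    abort_field("test_set", "must contain both classes")
  trajs <- sweep_trajectories(models, test_set, base_config)
  rows <- lapply(taus, function(tau) {
    pred <- vapply(seq_len(nrow(test_set)), function(i) {
      sweep_decide(models, test_set$pixels[[i]], trajs[[i]], tau,
                   extra_steps, base_config$max_steps, base_config$alpha)$is_ood
    }, logical(1))
    mr <- metrics_from_confusion(confusion_matrix(truth, pred))
    tibble::tibble(loss_threshold = tau,
                   extra_steps = as.integer(extra_steps),
                   accuracy = mr$accuracy, precision = mr$precision,
                   recall = mr$recall, f1 = mr$f1)
  })
  dplyr::bind_rows(rows)
}

#' Replicate detector accuracies across z seeds
#'
#' Latent initialisation is the only stochastic element at test time, so
#' replicates are defined by independent z seeds derived from
#' `base_config$z_seed`. One sweep is run per replicate.
#'
#' @inheritParams sweep_detector
#' @param n_replicates Number of replicate sweeps.
#' @return Tibble: `replicate`, `loss_threshold`, `extra_steps`, `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
detector_accuracy_replicates <- function(models, test_set, taus,
                                         extra_steps = 95L,
                                         base_config = inversion_config(),
                                         n_replicates = 3L,
                                         id_label = "FRONTAL") {
  rows <- lapply(seq_len(n_replicates), function(r) {
    cfg <- base_config
    cfg$z_seed <- derive_seed(base_config$z_seed, 104729L + r)
    sw <- sweep_detector(models, test_set, taus, extra_steps, cfg, id_label)
    sw$replicate <- r
    sw
  })
  dplyr::bind_rows(rows)[, c("replicate", "loss_threshold", "extra_steps",
                             "accuracy", "precision", "recall", "f1")]
}

#' One-way ANOVA over replicate accuracies
#'
#' Delegates to [anova_oneway()]; with 5 hyperparameter settings of 3
#' replicates each the degrees of freedom are (4, 10).
#'
#' @param accuracy_table Named list (or tibble with `loss_threshold` and
#'   `accuracy` columns, e.g. from [detector_accuracy_replicates()]) mapping
#'   each setting to its replicate accuracies.
#' @return An `anova_result`.
#' @export
anova_over_replicates <- function(accuracy_table) {
  if (is.data.frame(accuracy_table)) {
    accuracy_table <- split(accuracy_table$accuracy,
                            accuracy_table$loss_threshold)
  }
  anova_oneway(accuracy_table)
}
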