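# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @export
tidy.ks_test_result <- function(x, ...) {
  tibble::tibble(statistic = x$d_statistic, p.value = x$p_value,
                 n1 = x$n1, n2 = x$n2,
                 method = "Two-sample Kolmogorov-Smirnov test")
}

#' @export
tidy.anova_result <- function(x, ...) {
  tibble::tibble(term = "between", df = x$df_between, df.residual = x$df_within,
                 statistic = x$f_statistic, p.value = x$p_value)
}

#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(statistic = x$f_statistic, p.value = x$p_value,
                 df = x$df_between, df.residual = x$df_within)
}

#' @export
tidy.detection_result <- function(x, ...) {
  tibble::tibble(is_ood = x$is_ood, p.value = x$ks$p_value,
                 statistic = x$ks$d_statistic,
                 loss = x$reconstruction_loss, failure_mode = x$failure_mode)
}

#' @export
tidy.inversion_result <- function(x, ...) {
  tibble::tibble(step = seq_along(x$loss_trace), loss = x$loss_trace)
}

#' @export
tidy.gan_train_trace <- function(x, ...) {
  tidyr_longer <- function(df) {
    tibble::tibble(step = rep(df$step, 2L),
                   network = rep(c("discriminator", "generator"),
                                 each = nrow(df)),
                   loss = c(df$d_loss, df$g_loss))
  }
  tidyr_longer(x$losses)
}

#' @export
glance.gan_models <- function(x, ...) {
  np <- function(p) sum(vapply(p, length, numeric(1)))
  tibble::tibble(resolution = x$config$resolution,
                 latent_dim = x$config$latent_dim,
                 base_feature_maps = x$config$base_feature_maps,
                 trained_steps = x$trained_steps,
                 n_params_generator = np(x$generator$par),
                 n_params_discriminator = np(x$discriminator$par))
}

#' @export
autoplot.gan_train_trace <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$loss,
                                   colour = .data$network)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "training step", y = "binary cross-entropy loss",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.inversion_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "inversion step", y = "reconstruction MSE") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.image_sample <- function(object, ...) {
  m <- object$pixels
  df <- tibble::tibble(row = rep(seq_len(nrow(m)), ncol(m)),
                       col = rep(seq_len(ncol(m)), each = nrow(m)),
                       value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(-1, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity",
                  title = object$label) +
    ggplot2::theme_void()
}

#' Plot a threshold-sweep metrics table
#'
#' @param sweep Tibble from [sweep_detector()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  long <- tibble::tibble(
    loss_threshold = rep(sweep$loss_threshold, 4L),
    metric = rep(c("accuracy", "precision", "recall", "f1"),
                 each = nrow(sweep)),
    value = c(sweep$accuracy, sweep$precision, sweep$recall, sweep$f1))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$loss_threshold,
                                     y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "loss threshold", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
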