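#' Configure the GAN
#'
#' Hyperparameters of the compact deep-convolutional GAN: a generator of
#' stacked transposed-convolution + batch-normalisation + ReLU blocks ending
#' in Tanh, against a discriminator of strided-convolution +
#' batch-normalisation + LeakyReLU blocks ending in a sigmoid. Defaults
#' follow the training recipe the detector was developed with: Adam at
#' learning rate 0.001 with betas (0.5, 0.999) and 999 alternating training
#' steps.
#'
#' @param latent_dim Dimension of the latent vector z (default 100).
#' @param resolution Square image side; must be `4 * 2^B` for integer
#'   `B >= 2` (16, 32, 64, ...), so each block halves/doubles the spatial
#'   side between 4 and `resolution`.
#' @param base_feature_maps Width multiplier of both networks (channel count
#'   of the outermost block).
#' @param learning_rate,beta1,beta2 Adam settings for both networks.
#' @param train_steps Number of alternating discriminator+generator updates.
#' @param batch_size Minibatch size.
#' @param seed Integer seed controlling weight init and batch sampling.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(latent_dim = 100L, resolution = 64L,
                       base_feature_maps = 64L, learning_rate = 0.001,
                       beta1 = 0.5, beta2 = 0.999, train_steps = 999L,
                       batch_size = 64L, seed = 0L) {
  check_number(latent_dim, "latent_dim", lower = 1, integerish = TRUE)
  check_number(resolution, "resolution", lower = 16, integerish = TRUE)
  B <- log2(resolution / 4)
  if (abs(B - round(B)) > 1e-9)
    abort_field("resolution", "must be 4 * 2^B for integer B (16, 32, 64, ...)")
  check_number(base_feature_maps, "base_feature_maps", lower = 1,
               integerish = TRUE)
  check_number(learning_rate, "learning_rate", lower = 1e-12)
  check_number(beta1, "beta1", lower = 1e-12, upper = 1 - 1e-12)
  check_number(beta2, "beta2", lower = 1e-12, upper = 1 - 1e-12)
  check_number(train_steps, "train_steps", lower = 0, integerish = TRUE)
  check_number(batch_size, "batch_size", lower = 1, integerish = TRUE)
  check_number(seed, "seed", integerish = TRUE)
  structure(list(latent_dim = as.integer(latent_dim),
                 resolution = as.integer(resolution),
                 base_feature_maps = as.integer(base_feature_maps),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 train_steps = as.integer(train_steps),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 n_blocks = as.integer(round(B))),
            class = "gan_config")
}

gen_channels <- function(cfg) cfg$base_feature_maps * 2^((cfg$n_blocks - 1):0)
dis_channels <- function(cfg) cfg$base_feature_maps * 2^(0:(cfg$n_blocks - 1))

#' Build generator/discriminator parameter sets
#'
#' Allocates both networks for `config` and applies the standard compact-GAN
#' weight initialisation: convolution-type weights from Normal(0, 0.02),
#' batch-normalisation scales from Normal(1, 0.02), shifts 0. Deterministic
#' given `config$seed`.
#'
#' @param config A [gan_config()].
#' @return An object of class `gan_models` with elements `generator`,
#'   `discriminator` (each a list of trainable parameters `par` and
#'   batch-norm running buffers `buf`), `config`, and `trained_steps`.
#' @export
build_gan <- function(config) {
  if (!inherits(config, "gan_config"))
    abort_field("config", "must be a gan_config")
  B <- config$n_blocks
  k2 <- 16L  # 4 x 4 kernels everywhere
  gch <- gen_channels(config)
  dch <- dis_channels(config)

  gpar <- list(proj_W = matrix(0, k2 * gch[1], config$latent_dim),
               proj_b = numeric(k2 * gch[1]),
               bn0_g = numeric(gch[1]), bn0_b = numeric(gch[1]))
  gbuf <- list(bn0_rm = numeric(gch[1]), bn0_rv = rep(1, gch[1]))
  for (j in seq_len(B - 1)) {
    gpar[[paste0("dec", j, "_W")]] <- matrix(0, gch[j], k2 * gch[j + 1])
    gpar[[paste0("dec", j, "_b")]] <- numeric(gch[j + 1])
    gpar[[paste0("bn", j, "_g")]] <- numeric(gch[j + 1])
    gpar[[paste0("bn", j, "_b")]] <- numeric(gch[j + 1])
    gbuf[[paste0("bn", j, "_rm")]] <- numeric(gch[j + 1])
    gbuf[[paste0("bn", j, "_rv")]] <- rep(1, gch[j + 1])
  }
  gpar$out_W <- matrix(0, gch[B], k2)
  gpar$out_b <- numeric(1)

  dpar <- list(conv1_W = matrix(0, dch[1], k2), conv1_b = numeric(dch[1]))
  dbuf <- list()
  for (j in 2:B) {
    dpar[[paste0("conv", j, "_W")]] <- matrix(0, dch[j], k2 * dch[j - 1])
    dpar[[paste0("conv", j, "_b")]] <- numeric(dch[j])
    dpar[[paste0("dbn", j, "_g")]] <- numeric(dch[j])
    dpar[[paste0("dbn", j, "_b")]] <- numeric(dch[j])
    dbuf[[paste0("dbn", j, "_rm")]] <- numeric(dch[j])
    dbuf[[paste0("dbn", j, "_rv")]] <- rep(1, dch[j])
  }
  dpar$out_W <- matrix(0, 1, k2 * dch[B])
  dpar$out_b <- numeric(1)

  models <- structure(list(generator = list(par = gpar, buf = gbuf),
                           discriminator = list(par = dpar, buf = dbuf),
                           config = config, trained_steps = 0L),
                      class = "gan_models")
  init_gan_weights(models, config$seed)
}

#' Re-initialise GAN weights
#'
#' @param models A [build_gan()] result.
#' @param seed Integer seed for the initialisation draws.
#' @return `models` with freshly drawn weights.
#' @export
init_gan_weights <- function(models, seed) {
  check_number(seed, "seed", integerish = TRUE)
  init_one <- function(par) {
    for (nm in names(par)) {
      n <- length(par[[nm]])
      if (grepl("_W$", nm)) {
        par[[nm]][] <- stats::rnorm(n, 0, 0.02)
      } else if (grepl("(^bn|^dbn).*_g$", nm)) {
        par[[nm]][] <- stats::rnorm(n, 1, 0.02)
      } else {
        par[[nm]][] <- 0
      }
    }
    par
  }
  with_seed_(seed, {
    models$generator$par <- init_one(models$generator$par)
    models$discriminator$par <- init_one(models$discriminator$par)
  })
  models
}

#' @export
print.gan_models <- function(x, ...) {
  np <- function(p) sum(vapply(p, length, numeric(1)))
  cat(sprintf(paste0("<gan_models> %dx%d, latent %d, width %d; ",
                     "G %d params, D %d params, trained %d steps\n"),
              x$config$resolution, x$config$resolution, x$config$latent_dim,
              x$config$base_feature_maps, np(x$generator$par),
              np(x$discriminator$par), x$trained_steps))
  invisible(x)
}

# ---- forward / backward passes ----------------------------------------------

# Z: (latent_dim x N). Returns list(out (1 x H*W*N), caches, buf); see
# R/nn.R for the channels-first batch layout.
g_fwd <- function(gen, cfg, Z, train = FALSE) {
  p <- gen$par
  buf <- gen$buf
  B <- cfg$n_blocks
  gch <- gen_channels(cfg)
  N <- ncol(Z)
  caches <- list()

  dn <- dense_fwd(Z, p$proj_W, p$proj_b, C = gch[1])
  caches$proj <- dn
  dims <- c(4L, 4L, N)
  bn <- bn_fwd(dn$out, list(g = p$bn0_g, b = p$bn0_b),
               list(rm = buf$bn0_rm, rv = buf$bn0_rv), train)
  caches$bn0 <- bn
  if (train) {
    buf$bn0_rm <- bn$buf$rm
    buf$bn0_rv <- bn$buf$rv
  }
  rl <- relu_fwd(bn$out)
  caches$relu0 <- rl
  h <- rl$out
  for (j in seq_len(B - 1)) {
    dc <- deconv_fwd(h, dims, p[[paste0("dec", j, "_W")]],
                     p[[paste0("dec", j, "_b")]])
    dims <- dc$odims
    caches[[paste0("dec", j)]] <- dc
    bn <- bn_fwd(dc$out,
                 list(g = p[[paste0("bn", j, "_g")]],
                      b = p[[paste0("bn", j, "_b")]]),
                 list(rm = buf[[paste0("bn", j, "_rm")]],
                      rv = buf[[paste0("bn", j, "_rv")]]), train)
    caches[[paste0("bn", j)]] <- bn
    if (train) {
      buf[[paste0("bn", j, "_rm")]] <- bn$buf$rm
      buf[[paste0("bn", j, "_rv")]] <- bn$buf$rv
    }
    rl <- relu_fwd(bn$out)
    caches[[paste0("relu", j)]] <- rl
    h <- rl$out
  }
  dc <- deconv_fwd(h, dims, p$out_W, p$out_b)
  caches$out <- dc
  th <- tanh_fwd(dc$out)
  caches$tanh <- th
  list(out = th$out, caches = caches, buf = buf)
}

# dout: gradient w.r.t. generator output. Returns list(grads, dZ).
g_bwd <- function(gen, cfg, caches, dout, param_grad = TRUE) {
  p <- gen$par
  B <- cfg$n_blocks
  grads <- list()
  dy <- tanh_bwd(dout, caches$tanh)
  g <- deconv_bwd(dy, p$out_W, caches$out, param_grad = param_grad)
  if (param_grad) {
    grads$out_W <- g$dW
    grads$out_b <- g$db
  }
  dy <- g$dx
  for (j in rev(seq_len(B - 1))) {
    dy <- relu_bwd(dy, caches[[paste0("relu", j)]])
    g <- bn_bwd(dy, list(g = p[[paste0("bn", j, "_g")]]),
                caches[[paste0("bn", j)]], param_grad = param_grad)
    if (param_grad) {
      grads[[paste0("bn", j, "_g")]] <- g$dg
      grads[[paste0("bn", j, "_b")]] <- g$db
    }
    dy <- g$dx
    g <- deconv_bwd(dy, p[[paste0("dec", j, "_W")]],
                    caches[[paste0("dec", j)]], param_grad = param_grad)
    if (param_grad) {
      grads[[paste0("dec", j, "_W")]] <- g$dW
      grads[[paste0("dec", j, "_b")]] <- g$db
    }
    dy <- g$dx
  }
  dy <- relu_bwd(dy, caches$relu0)
  g <- bn_bwd(dy, list(g = p$bn0_g), caches$bn0, param_grad = param_grad)
  if (param_grad) {
    grads$bn0_g <- g$dg
    grads$bn0_b <- g$db
  }
  g <- dense_bwd(g$dx, p$proj_W, caches$proj, param_grad = param_grad)
  if (param_grad) {
    grads$proj_W <- g$dW
    grads$proj_b <- g$db
  }
  list(grads = grads, dZ = g$dx)
}

# X: (1 x H*W*N) channels-first matrix; dims = c(H, W, N).
# Returns list(logits (length N), caches, buf).
d_fwd <- function(dis, cfg, X, dims, train = FALSE) {
  p <- dis$par
  buf <- dis$buf
  B <- cfg$n_blocks
  caches <- list()
  cv <- conv_fwd(X, dims, p$conv1_W, p$conv1_b)
  caches$conv1 <- cv
  lr <- lrelu_fwd(cv$out)
  caches$lrelu1 <- lr
  h <- lr$out
  for (j in 2:B) {
    cv <- conv_fwd(h, cv$odims, p[[paste0("conv", j, "_W")]],
                   p[[paste0("conv", j, "_b")]])
    caches[[paste0("conv", j)]] <- cv
    bn <- bn_fwd(cv$out,
                 list(g = p[[paste0("dbn", j, "_g")]],
                      b = p[[paste0("dbn", j, "_b")]]),
                 list(rm = buf[[paste0("dbn", j, "_rm")]],
                      rv = buf[[paste0("dbn", j, "_rv")]]), train)
    caches[[paste0("dbn", j)]] <- bn
    if (train) {
      buf[[paste0("dbn", j, "_rm")]] <- bn$buf$rm
      buf[[paste0("dbn", j, "_rv")]] <- bn$buf$rv
    }
    lr <- lrelu_fwd(bn$out)
    caches[[paste0("lrelu", j)]] <- lr
    h <- lr$out
  }
  cv <- conv_fwd(h, cv$odims, p$out_W, p$out_b, stride = 1L, pad = 0L)
  caches$out <- cv
  list(logits = as.vector(cv$out), caches = caches, buf = buf)
}

# dlogits: length-N gradient at the logit. Returns list(grads, dX).
d_bwd <- function(dis, cfg, caches, dlogits, input_grad = FALSE,
                  param_grad = TRUE) {
  p <- dis$par
  B <- cfg$n_blocks
  grads <- list()
  dy <- matrix(dlogits, nrow = 1L)
  g <- conv_bwd(dy, p$out_W, caches$out, param_grad = param_grad)
  if (param_grad) {
    grads$out_W <- g$dW
    grads$out_b <- g$db
  }
  dy <- g$dx
  for (j in B:2) {
    dy <- lrelu_bwd(dy, caches[[paste0("lrelu", j)]])
    g <- bn_bwd(dy, list(g = p[[paste0("dbn", j, "_g")]]),
                caches[[paste0("dbn", j)]], param_grad = param_grad)
    if (param_grad) {
      grads[[paste0("dbn", j, "_g")]] <- g$dg
      grads[[paste0("dbn", j, "_b")]] <- g$db
    }
    dy <- g$dx
    g <- conv_bwd(dy, p[[paste0("conv", j, "_W")]],
                  caches[[paste0("conv", j)]], param_grad = param_grad)
    if (param_grad) {
      grads[[paste0("conv", j, "_W")]] <- g$dW
      grads[[paste0("conv", j, "_b")]] <- g$db
    }
    dy <- g$dx
  }
  dy <- lrelu_bwd(dy, caches$lrelu1)
  g <- conv_bwd(dy, p$conv1_W, caches$conv1, input_grad = input_grad,
                param_grad = param_grad)
  if (param_grad) {
    grads$conv1_W <- g$dW
    grads$conv1_b <- g$db
  }
  list(grads = grads, dX = g$dx)
}

# ---- training ---------------------------------------------------------------

#' Train the GAN on in-distribution images
#'
#' Runs `config$train_steps` alternating updates: a discriminator step on a
#' real minibatch (target 1) and a generated minibatch (target 0) under
#' binary cross-entropy, then a generator step trained against target 1 (the
#' non-saturating objective). Both networks use Adam with the config's
#' learning rate and betas. A fixed monitor batch of latent vectors is drawn
#' at the start so the generator's progress can be visualised on a constant
#' probe set. Bitwise reproducible given `config$seed` and the input order.
#'
#' @param models A [build_gan()] result.
#' @param images In-distribution (single class) images: a dataset tibble with
#'   a `pixels` list-column, a list of [image_sample()]s/matrices, or an
#'   `image_sample`.
#' @param config Optional [gan_config()]; defaults to `models$config`.
#' @return A list with `models` (trained) and `trace` (class
#'   `gan_train_trace`: per-step losses plus the monitor latents).
#' @export
train_gan <- function(models, images, config = NULL) {
  cfg <- config %||% models$config
  if (!inherits(models, "gan_models"))
    abort_field("models", "must be a gan_models")
  X_all <- as_image_batch(images)  # errors on empty input
  d <- dim(X_all)
  if (d[1] != cfg$resolution || d[2] != cfg$resolution)
    abort_field("images", sprintf("resolution %dx%d does not match config %d",
                                  d[1], d[2], cfg$resolution))
  n_img <- d[4]
  gen <- models$generator
  dis <- models$discriminator
  d_losses <- numeric(cfg$train_steps)
  g_losses <- numeric(cfg$train_steps)

  with_seed_(cfg$seed, {
    monitor_Z <- matrix(stats::rnorm(cfg$latent_dim * 16L), cfg$latent_dim)
    if (cfg$train_steps > 0) {
      opt_g <- adam_init(gen$par)
      opt_d <- adam_init(dis$par)
      bdims <- c(d[1], d[2], cfg$batch_size)
      for (step in seq_len(cfg$train_steps)) {
        idx <- sample.int(n_img, cfg$batch_size, replace = n_img < cfg$batch_size)
        X_real <- matrix(X_all[, , , idx, drop = FALSE], nrow = 1L)
        Z <- matrix(stats::rnorm(cfg$latent_dim * cfg$batch_size),
                    cfg$latent_dim)

        # discriminator step: real (target 1) + generated (target 0)
        gf <- g_fwd(gen, cfg, Z, train = TRUE)
        gen$buf <- gf$buf
        fr <- d_fwd(dis, cfg, X_real, bdims, train = TRUE)
        dis$buf <- fr$buf
        br <- bce_logits(fr$logits, 1)
        gr <- d_bwd(dis, cfg, fr$caches, br$grad)
        ff <- d_fwd(dis, cfg, gf$out, bdims, train = TRUE)
        dis$buf <- ff$buf
        bf <- bce_logits(ff$logits, 0)
        gfk <- d_bwd(dis, cfg, ff$caches, bf$grad)
        dgr <- Map(`+`, gr$grads, gfk$grads[names(gr$grads)])
        upd <- adam_step(dis$par, dgr, opt_d, cfg$learning_rate, cfg$beta1,
                         cfg$beta2)
        dis$par <- upd$params
        opt_d <- upd$state
        d_losses[step] <- br$loss + bf$loss

        # generator step: fool the updated discriminator (target 1)
        f2 <- d_fwd(dis, cfg, gf$out, bdims, train = TRUE)
        dis$buf <- f2$buf
        bg <- bce_logits(f2$logits, 1)
        din <- d_bwd(dis, cfg, f2$caches, bg$grad, input_grad = TRUE,
                     param_grad = FALSE)
        gb <- g_bwd(gen, cfg, gf$caches, din$dX)
        upd <- adam_step(gen$par, gb$grads, opt_g, cfg$learning_rate,
                         cfg$beta1, cfg$beta2)
        gen$par <- upd$params
        opt_g <- upd$state
        g_losses[step] <- bg$loss

        if (!is.finite(d_losses[step]) || !is.finite(g_losses[step]))
          stop(sprintf("training diverged at step %d (non-finite loss)", step),
               call. = FALSE)
      }
    }
  })

  models$generator <- gen
  models$discriminator <- dis
  models$trained_steps <- models$trained_steps + cfg$train_steps
  models$config <- cfg
  trace <- structure(list(losses = tibble::tibble(step = seq_len(cfg$train_steps),
                                                  d_loss = d_losses,
                                                  g_loss = g_losses),
                          monitor_latents = monitor_Z,
                          monitor_images_every = 100L),
                     class = "gan_train_trace")
  list(models = models, trace = trace)
}

#' Generate an image from a latent vector
#'
#' Evaluates the generator in inference mode (batch normalisation uses its
#' running statistics), so the output is a fixed deterministic function of z.
#'
#' @param models A (typically trained) [gan_models] object.
#' @param z Numeric latent vector of length `latent_dim`, or a
#'   `latent_dim x n` matrix for a batch.
#' @return An [image_sample()] (vector z) or a list of them (matrix z).
#' @export
gan_generate <- function(models, z) {
  cfg <- models$config
  single <- is.null(dim(z))
  Z <- if (single) matrix(z, ncol = 1) else z
  if (nrow(Z) != cfg$latent_dim)
    abort_field("z", sprintf("must have length %d", cfg$latent_dim))
  out <- g_fwd(models$generator, cfg, Z, train = FALSE)$out
  res <- cfg$resolution
  arr <- array(out, c(res, res, ncol(Z)))
  samples <- lapply(seq_len(ncol(Z)),
                    function(i) image_sample(arr[, , i], label = "UNKNOWN"))
  if (single) samples[[1]] else samples
}

#' Discriminator output probability for images
#'
#' @param models A [gan_models] object.
#' @param images Images accepted by [train_gan()].
#' @return Numeric vector of probabilities in (0, 1), one per image.
#' @export
gan_discriminate <- function(models, images) {
  X <- as_image_batch(images)
  d <- dim(X)
  sigmoid(d_fwd(models$discriminator, models$config, matrix(X, nrow = 1L),
                c(d[1], d[2], d[4]), train = FALSE)$logits)
}

#' Save / load a GAN checkpoint
#'
#' The checkpoint is a single file holding both parameter sets, the
#' batch-norm running buffers, the config, and the trained step count.
#'
#' @param models A [gan_models] object.
#' @param path Checkpoint file path.
#' @return `save_gan` returns `path` invisibly; `load_gan` the restored
#'   `gan_models`.
#' @export
save_gan <- function(models, path) {
  saveRDS(models, path)
  invisible(path)
}

#' @rdname save_gan
#' @export
load_gan <- function(path) {
  models <- readRDS(path)
  if (!inherits(models, "gan_models"))
    stop(sprintf("'%s' is not a GAN checkpoint", path), call. = FALSE)
  models
}
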