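# Network primitives: convolution against a naive oracle, and full-network
# gradients against central finite differences.

# Naive direct convolution oracle for a 1-channel input, channels-first
# layout: out[o, pos] = sum_kh,kw W[o, .] * x[window] + b[o].
conv_naive <- function(xm, H, W, Wm, b, stride, pad, k) {
  oH <- (H + 2 * pad - k) %/% stride + 1
  oW <- (W + 2 * pad - k) %/% stride + 1
  x <- matrix(xm, H, W)
  xp <- matrix(0, H + 2 * pad, W + 2 * pad)
  xp[pad + seq_len(H), pad + seq_len(W)] <- x
  out <- matrix(0, nrow(Wm), oH * oW)
  for (oh in seq_len(oH)) for (ow in seq_len(oW)) {
    win <- xp[(oh - 1) * stride + seq_len(k), (ow - 1) * stride + seq_len(k)]
    out[, (ow - 1) * oH + oh] <- Wm %*% as.vector(win) + b
  }
  out
}

test_that("GEMM-lowered convolution equals direct convolution", {
  set.seed(10)
  for (i in 1:5) {
    H <- 8L
    xm <- matrix(rnorm(H * H), nrow = 1)
    Wm <- matrix(rnorm(3 * 16), nrow = 3)
    b <- rnorm(3)
    got <- latentks:::conv_fwd(xm, c(H, H, 1L), Wm, b)$out
    want <- conv_naive(xm, H, H, Wm, b, stride = 2, pad = 1, k = 4)
    expect_equal(got, want)
  }
})

test_that("col2im is the exact adjoint of im2col", {
  # <im2col(x), C> == <x, col2im(C)> for random C: the identity the
  # transposed-convolution forward/backward passes rest on.
  set.seed(11)
  H <- 8L
  Cch <- 2L
  N <- 3L
  x <- matrix(rnorm(Cch * H * H * N), nrow = Cch)
  cols <- latentks:::im2col_cpp(x, H, H, N, 4L, 2L, 1L)
  Cr <- matrix(rnorm(length(cols)), nrow(cols))
  lhs <- sum(cols * Cr)
  back <- latentks:::col2im_cpp(Cr, H, H, Cch, N, 4L, 2L, 1L)
  expect_equal(lhs, sum(x * back))
})

test_that("transposed convolution doubles the spatial side and is adjoint", {
  set.seed(12)
  Cin <- 3L
  Cout <- 2L
  x4 <- matrix(rnorm(Cin * 16), nrow = Cin)           # 4 x 4 input grid
  Wd <- matrix(rnorm(Cin * 16 * Cout), nrow = Cin)
  up <- latentks:::deconv_fwd(x4, c(4L, 4L, 1L), Wd, rep(0, Cout))
  expect_identical(up$odims[1:2], c(8L, 8L))
  expect_identical(dim(up$out), c(Cout, 64L))
  # <deconv(x), y> == <x, conv-with-same-weight(y)>
  y <- matrix(rnorm(Cout * 64), nrow = Cout)
  lhs <- sum(up$out * y)
  cols_y <- latentks:::im2col_cpp(y, 8L, 8L, 1L, 4L, 2L, 1L)
  rhs <- sum(x4 * (Wd %*% cols_y))
  expect_equal(lhs, rhs)
})

test_that("loss gradient in z passes a central finite-difference check", {
  m <- tiny_gan()
  x <- generate_phantom(phantom_spec("FRONTAL", 16, 0.1, 0.1, 2))$pixels
  set.seed(4)
  z <- rnorm(8)
  lg <- latentks:::z_loss_grad(m, z, x)
  num <- vapply(1:8, function(i) {
    e <- rep(0, 8)
    e[i] <- 1e-5
    (latentks:::z_loss_grad(m, z + e, x)$loss -
       latentks:::z_loss_grad(m, z - e, x)$loss) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(num - lg$grad)) / max(abs(num)), 1e-4)
})

test_that("all parameter gradients pass finite-difference checks", {
  m <- tiny_gan()
  cfg <- m$config
  set.seed(9)
  Z <- matrix(rnorm(8 * 3), 8)
  X <- matrix(rnorm(16 * 16 * 3, 0, 0.5), nrow = 1)
  dims <- c(16L, 16L, 3L)

  gf <- latentks:::g_fwd(m$generator, cfg, Z, train = TRUE)
  dout <- 2 * (gf$out - X) / length(X)
  gb <- latentks:::g_bwd(m$generator, cfg, gf$caches, dout)
  gobj <- function(par) {
    gen <- m$generator
    gen$par <- par
    mean((latentks:::g_fwd(gen, cfg, Z, train = TRUE)$out - X)^2)
  }
  # h = 1e-6: perturbing batch-norm shifts can flip downstream ReLU masks
  # (kinks), whose finite-difference error scales with h
  set.seed(2)
  for (nm in names(gb$grads)) {
    i <- sample(length(m$generator$par[[nm]]), 1)
    p1 <- m$generator$par
    p1[[nm]][i] <- p1[[nm]][i] + 1e-6
    p2 <- m$generator$par
    p2[[nm]][i] <- p2[[nm]][i] - 1e-6
    num <- (gobj(p1) - gobj(p2)) / 2e-6
    expect_equal(gb$grads[[nm]][i], num, tolerance = 1e-3,
                 label = paste("generator grad", nm))
  }

  ff <- latentks:::d_fwd(m$discriminator, cfg, X, dims, train = TRUE)
  bl <- latentks:::bce_logits(ff$logits, 1)
  db <- latentks:::d_bwd(m$discriminator, cfg, ff$caches, bl$grad,
                         input_grad = TRUE)
  dobj <- function(par) {
    dis <- m$discriminator
    dis$par <- par
    lg <- latentks:::d_fwd(dis, cfg, X, dims, train = TRUE)$logits
    latentks:::bce_logits(lg, 1)$loss
  }
  for (nm in names(db$grads)) {
    i <- sample(length(m$discriminator$par[[nm]]), 1)
    p1 <- m$discriminator$par
    p1[[nm]][i] <- p1[[nm]][i] + 1e-5
    p2 <- m$discriminator$par
    p2[[nm]][i] <- p2[[nm]][i] - 1e-5
    num <- (dobj(p1) - dobj(p2)) / 2e-5
    expect_equal(db$grads[[nm]][i], num, tolerance = 1e-4,
                 label = paste("discriminator grad", nm))
  }

  # input gradient (the path the generator step differentiates through)
  set.seed(3)
  for (i in sample(length(X), 4)) {
    X1 <- X
    X1[i] <- X1[i] + 1e-5
    X2 <- X
    X2[i] <- X2[i] - 1e-5
    l1 <- latentks:::bce_logits(
      latentks:::d_fwd(m$discriminator, cfg, X1, dims, TRUE)$logits, 1)$loss
    l2 <- latentks:::bce_logits(
      latentks:::d_fwd(m$discriminator, cfg, X2, dims, TRUE)$logits, 1)$loss
    expect_equal(db$dX[i], (l1 - l2) / 2e-5, tolerance = 1e-4)
  }
})
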