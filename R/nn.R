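# Low-level neural-network primitives.
#
# Image batches travel as channels-first matrices: (C) x (H*W*N), columns
# ordered h fastest, then w, then n (see src/convtools.cpp). Convolutions are
# lowered to GEMM via im2col/col2im; with one row per channel, batch
# normalisation, bias addition and channel scaling are plain row-recycled
# vector arithmetic, so no transposes occur anywhere in a forward/backward
# pass. Each *_fwd returns the output plus the cache its *_bwd needs;
# backward functions can skip parameter or input gradients when the caller
# does not need them.

# ---- strided convolution (k x k, stride s, zero pad p) ----------------------

# Wm: (outC) x (k*k*inC); rows index output channels, columns ordered
# kh fastest, then kw, then input channel (matching im2col row order).
# dims: c(H, W, N) of the input batch.
conv_fwd <- function(x, dims, Wm, b, stride = 2L, pad = 1L, k = 4L) {
  cols <- im2col_cpp(x, dims[1], dims[2], dims[3], k, stride, pad)
  oH <- (dims[1] + 2L * pad - k) %/% stride + 1L
  oW <- (dims[2] + 2L * pad - k) %/% stride + 1L
  out <- Wm %*% cols + b  # b (length outC) recycles down rows
  list(out = out, odims = c(oH, oW, dims[3]), cols = cols, dims = dims,
       k = k, stride = stride, pad = pad)
}

conv_bwd <- function(dy, Wm, cache, input_grad = TRUE, param_grad = TRUE) {
  g <- list()
  if (param_grad) {
    g$dW <- tcrossprod(dy, cache$cols)
    g$db <- rowSums(dy)
  }
  if (input_grad) {
    d <- cache$dims
    inC <- ncol(Wm) %/% (cache$k * cache$k)
    g$dx <- col2im_cpp(crossprod(Wm, dy), d[1], d[2], inC, d[3],
                       cache$k, cache$stride, cache$pad)
  }
  g
}

# ---- transposed convolution (fractionally strided) --------------------------

# Wd: (inC) x (k*k*outC). Forward is the adjoint of conv_fwd: output spatial
# side is (H-1)*stride - 2*pad + k (doubling for k=4, s=2, p=1).
deconv_fwd <- function(x, dims, Wd, b, stride = 2L, pad = 1L, k = 4L) {
  outC <- ncol(Wd) %/% (k * k)
  oH <- (dims[1] - 1L) * stride - 2L * pad + k
  oW <- (dims[2] - 1L) * stride - 2L * pad + k
  cols <- crossprod(Wd, x)
  out <- col2im_cpp(cols, oH, oW, outC, dims[3], k, stride, pad) + b
  list(out = out, x = x, odims = c(oH, oW, dims[3]), dims = dims,
       outC = outC, k = k, stride = stride, pad = pad)
}

deconv_bwd <- function(dy, Wd, cache, input_grad = TRUE, param_grad = TRUE) {
  od <- cache$odims
  cols_dy <- im2col_cpp(dy, od[1], od[2], od[3],
                        cache$k, cache$stride, cache$pad)
  g <- list()
  if (param_grad) {
    g$dW <- tcrossprod(cache$x, cols_dy)
    g$db <- rowSums(dy)
  }
  if (input_grad) g$dx <- Wd %*% cols_dy
  g
}

# ---- dense projection (latent -> 4 x 4 feature block) -----------------------

# W: (C*16) x (latent), rows ordered channel fastest, then h, then w, so the
# output reshapes to the channels-first (C) x (16*N) layout by reinterpreting
# the same memory.
dense_fwd <- function(z, W, b, C) {
  y <- W %*% z + b
  list(out = matrix(y, nrow = C), z = z, C = C)
}

dense_bwd <- function(dy, W, cache, input_grad = TRUE, param_grad = TRUE) {
  dy_flat <- matrix(as.vector(dy), nrow = nrow(W))
  g <- list()
  if (param_grad) {
    g$dW <- tcrossprod(dy_flat, cache$z)
    g$db <- rowSums(dy_flat)
  }
  if (input_grad) g$dx <- crossprod(W, dy_flat)
  g
}

# ---- batch normalisation (per channel = per row) ----------------------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1  # running <- (1 - m) * running + m * batch

# p: list(g, b); buf: list(rm, rv). Returns updated buffers in training mode.
bn_fwd <- function(x, p, buf, train) {
  if (train) {
    m <- rowMeans(x)
    v <- rowMeans(x * x) - m * m
    v[v < 0] <- 0
    M <- ncol(x)
    ub <- if (M > 1) v * M / (M - 1) else v
    buf$rm <- (1 - BN_MOMENTUM) * buf$rm + BN_MOMENTUM * m
    buf$rv <- (1 - BN_MOMENTUM) * buf$rv + BN_MOMENTUM * ub
  } else {
    m <- buf$rm
    v <- buf$rv
  }
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- (x - m) * istd
  out <- xhat * p$g + p$b
  list(out = out, xhat = xhat, istd = istd, train = train, buf = buf)
}

bn_bwd <- function(dy, p, cache, param_grad = TRUE) {
  g <- list()
  if (param_grad) {
    g$dg <- rowSums(dy * cache$xhat)
    g$db <- rowSums(dy)
  }
  dxhat <- dy * p$g
  if (cache$train) {
    t1 <- rowMeans(dxhat)
    t2 <- rowMeans(dxhat * cache$xhat)
    g$dx <- (dxhat - t1 - cache$xhat * t2) * cache$istd
  } else {
    g$dx <- dxhat * cache$istd
  }
  g
}

# ---- activations ------------------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}
relu_bwd <- function(dy, cache) dy * cache$mask

lrelu_fwd <- function(x, a = 0.2) {
  mask <- x > 0
  list(out = x * (mask + a * !mask), mask = mask, a = a)
}
lrelu_bwd <- function(dy, cache) dy * (cache$mask + cache$a * !cache$mask)

tanh_fwd <- function(x) {
  y <- tanh(x)
  list(out = y, y = y)
}
tanh_bwd <- function(dy, cache) dy * (1 - cache$y * cache$y)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable binary cross-entropy on logits; target t in {0, 1}.
# Returns the mean loss and the per-element logit gradient of the mean.
bce_logits <- function(logits, target) {
  sp <- pmax(logits, 0) + log1p(exp(-abs(logits)))
  loss <- mean(sp - target * logits)
  grad <- (sigmoid(logits) - target) / length(logits)
  list(loss = loss, grad = grad)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) {
    z <- p
    z[] <- 0
    z
  })
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
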