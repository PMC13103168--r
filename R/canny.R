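# Classical Canny edge operator: Gaussian smoothing, Sobel gradients,
# non-maximum suppression, double-threshold hysteresis. Hand-implemented
# because no installed R package provides it; inputs are small square
# matrices so dense linear algebra is ample.

# Border-replicating shift of a matrix by (dr, dc).
shift_mat <- function(m, dr, dc) {
  n <- nrow(m)
  p <- ncol(m)
  ri <- pmin(pmax(seq_len(n) + dr, 1L), n)
  ci <- pmin(pmax(seq_len(p) + dc, 1L), p)
  m[ri, ci, drop = FALSE]
}

# Separable Gaussian blur via a row-normalised band matrix (truncated kernel
# renormalised at the borders).
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  n <- nrow(m)
  S <- matrix(0, n, n)
  for (o in -r:r) {
    idx <- seq_len(n)
    j <- idx + o
    ok <- j >= 1 & j <= n
    S[cbind(idx[ok], j[ok])] <- k[o + r + 1]
  }
  S <- S / rowSums(S)
  S %*% m %*% t(S)
}

canny_edges <- function(m, sigma = 1, low = 0.1, high = 0.3) {
  g <- gauss_blur(m, sigma)
  # Sobel gradients (x = columns, y = rows)
  gx <- (shift_mat(g, -1, 1) + 2 * shift_mat(g, 0, 1) + shift_mat(g, 1, 1)) -
        (shift_mat(g, -1, -1) + 2 * shift_mat(g, 0, -1) + shift_mat(g, 1, -1))
  gy <- (shift_mat(g, 1, -1) + 2 * shift_mat(g, 1, 0) + shift_mat(g, 1, 1)) -
        (shift_mat(g, -1, -1) + 2 * shift_mat(g, -1, 0) + shift_mat(g, -1, 1))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(m), ncol(m)))
  # quantise gradient direction to 0/45/90/135 degrees
  ang <- atan2(gy, gx) * 180 / pi
  ang[ang < 0] <- ang[ang < 0] + 180
  sector <- ifelse(ang < 22.5 | ang >= 157.5, 0L,
                   ifelse(ang < 67.5, 45L, ifelse(ang < 112.5, 90L, 135L)))
  nb1 <- mag
  nb2 <- mag
  for (s in c(0L, 45L, 90L, 135L)) {
    off <- switch(as.character(s),
                  "0" = c(0, 1), "45" = c(1, 1), "90" = c(1, 0),
                  "135" = c(1, -1))
    sel <- sector == s
    a <- shift_mat(mag, off[1], off[2])
    b <- shift_mat(mag, -off[1], -off[2])
    nb1[sel] <- a[sel]
    nb2[sel] <- b[sel]
  }
  nms <- mag >= nb1 & mag >= nb2
  strong <- nms & mag >= high
  weak <- nms & mag >= low & !strong
  # hysteresis: weak pixels survive only when 8-connected to strong ones
  repeat {
    nbr <- strong
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nbr <- nbr | shift_mat(strong, dr, dc)
    }
    grow <- weak & nbr
    if (!any(grow)) break
    strong <- strong | grow
    weak <- weak & !grow
  }
  strong
}
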