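#' Specify a chest-phantom image
#'
#' Describes one procedurally generated grayscale phantom from two visually
#' distinct families standing in for the two radiographic views: `FRONTAL`
#' phantoms are left-right symmetric (two dark lung-field blobs flanking a
#' bright central spine band over a diaphragm shelf), `LATERAL` phantoms are
#' asymmetric (one dominant dark lobe with an off-centre bright spine band).
#' The two families have distinct pixel-intensity distributions, which is the
#' separability the reconstruction-based detector exploits.
#'
#' @param view_class `"FRONTAL"` or `"LATERAL"`.
#' @param resolution Square image side in pixels; at least 16 and a multiple
#'   of 16 (so the strided generator/discriminator stacks divide it evenly).
#' @param noise_sigma Standard deviation of additive Gaussian pixel noise on
#'   the \[-1, 1\] intensity scale, in \[0, 0.5\].
#' @param jitter Fractional random perturbation of the structure geometry
#'   (blob centres, widths, amplitudes), in \[0, 0.5\].
#' @param seed Integer seed; phantoms are bitwise reproducible given the spec.
#' @return An object of class `phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(view_class, resolution = 64L, noise_sigma = 0.01,
                         jitter = 0.2, seed = 0L) {
  if (!is.character(view_class) || length(view_class) != 1L ||
      !view_class %in% c("FRONTAL", "LATERAL"))
    abort_field("view_class", "must be \"FRONTAL\" or \"LATERAL\"")
  check_number(resolution, "resolution", lower = 16, integerish = TRUE)
  if (resolution %% 16 != 0)
    abort_field("resolution", "must be a multiple of 16")
  check_number(noise_sigma, "noise_sigma", lower = 0, upper = 0.5)
  check_number(jitter, "jitter", lower = 0, upper = 0.5)
  check_number(seed, "seed", integerish = TRUE)
  structure(list(view_class = view_class, resolution = as.integer(resolution),
                 noise_sigma = noise_sigma, jitter = jitter,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Exactly antisymmetric horizontal coordinate grid: xs[i] == -xs[R + 1 - i]
# bitwise, so the noise-free frontal template is mirror symmetric to the bit.
phantom_axes <- function(R) {
  half <- (seq_len(R %/% 2) - 0.5) * (2 / R)
  list(xs = c(-rev(half), half),
       ys = (seq_len(R) - 0.5) * (2 / R) - 1)
}

gauss2 <- function(X, Y, cx, cy, wx, wy, amp) {
  amp * exp(-(((X - cx) / wx)^2 + ((Y - cy) / wy)^2))
}

# Noise-free frontal structure: bright central spine band, mediastinal glow,
# diaphragm shelf, two dark lung fields. Mirrored structure pairs are summed
# pairwise before being added to the symmetric part so the jitter-free image
# is mirror symmetric to the bit. u: 12 uniform(-1, 1) draws; j scales them.
frontal_structure <- function(X, Y, bg, j, u) {
  sym <- 0.05 + bg +
    0.40 * exp(-(X / (0.09 * (1 + 0.5 * j * u[1])))^2) +
    gauss2(X, Y, 0, -0.1 + 0.2 * j * u[2], 0.40, 0.80, 0.15) +
    0.25 * exp(-((Y - (0.72 + 0.2 * j * u[3])) / 0.18)^2)
  lungL <- gauss2(X, Y, -0.45 + 0.25 * j * u[4], -0.10 + 0.25 * j * u[5],
                  0.26 * (1 + 0.5 * j * u[6]), 0.45, -0.70)
  lungR <- gauss2(X, Y, 0.45 + 0.25 * j * u[7], -0.10 + 0.25 * j * u[8],
                  0.26 * (1 + 0.5 * j * u[9]), 0.45, -0.70)
  sym + (lungL + lungR)
}

# Noise-free lateral structure: one dominant dark lobe, off-centre bright
# spine band, shoulder band, diaphragm glow; left-right asymmetric.
lateral_structure <- function(X, Y, bg, j, u) {
  0.07 + bg +
    gauss2(X, Y, -0.15 + 0.25 * j * u[1], -0.05 + 0.25 * j * u[2],
           0.42 * (1 + 0.5 * j * u[3]), 0.58, -0.70) +
    0.42 * exp(-((X - (0.55 + 0.2 * j * u[4])) / 0.13)^2) +
    0.25 * exp(-((Y - (-0.85 + 0.2 * j * u[5])) / 0.30)^2) +
    gauss2(X, Y, -0.20 + 0.2 * j * u[6], 0.70 + 0.2 * j * u[7],
           0.90, 0.25, 0.22)
}

#' Generate one phantom image
#'
#' Deterministic given the spec: geometry jitter and pixel noise are drawn
#' from a stream seeded by `spec$seed`. With `noise_sigma = jitter = 0` the
#' frontal template is exactly mirror symmetric and the lateral template has a
#' left-right asymmetry residual well above 0.2.
#'
#' @param spec A [phantom_spec()].
#' @return An [image_sample()] with pixels clipped to \[-1, 1\] and the spec's
#'   view class as label.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec"))
    abort_field("spec", "must be a phantom_spec")
  R <- spec$resolution
  ax <- phantom_axes(R)
  X <- matrix(ax$xs, R, R, byrow = TRUE)   # rows = y, cols = x
  Y <- matrix(ax$ys, R, R)
  j <- spec$jitter
  # Smooth illumination field (vertical exposure gradient plus radial
  # vignette), shared by both views. It spreads the intensity histogram over
  # a broad range the way real radiograph exposure falloff does; without it
  # the flat background would concentrate pixel mass at a single intensity.
  # Structure amplitudes are scaled so the noise-free image stays strictly
  # inside (-1, 1): clipping would pile delta mass onto the boundary values,
  # which a Tanh-output generator can never reproduce and which would
  # dominate the pixel-distribution KS statistic. Both background terms are
  # bitwise invariant under horizontal flip.
  bg <- 0.30 * Y - 0.20 * (X^2 + Y^2)
  with_seed_(spec$seed, {
    u <- stats::runif(12L, -1, 1)  # geometry perturbations, scaled by jitter
    if (spec$view_class == "FRONTAL") {
      px <- frontal_structure(X, Y, bg, j, u)
    } else {
      # Real frontal and lateral radiographs share near-identical global
      # intensity statistics; the views differ in spatial arrangement, not
      # in their histograms. To emulate that subtlety, the lateral
      # structure's intensities are rank-matched onto a reference frontal
      # structure (monotone remap, so spatial structure is untouched) and
      # blended 3:1 with the original, leaving only a weak residual
      # histogram signal for summary-statistic detectors.
      s_lat <- lateral_structure(X, Y, bg, j, u)
      u_ref <- with_seed_(derive_seed(spec$seed, 424243L),
                          stats::runif(12L, -1, 1))
      f_ref <- frontal_structure(X, Y, bg, j, u_ref)
      matched <- s_lat
      matched[order(s_lat)] <- sort(f_ref)
      px <- 0.9 * matched + 0.1 * s_lat
    }
    if (spec$noise_sigma > 0)
      px <- px + matrix(stats::rnorm(R * R, 0, spec$noise_sigma), R, R)
    px <- pmin(pmax(px, -1), 1)
    image_sample(px, spec$view_class)
  })
}

#' Generate a labelled phantom dataset
#'
#' Produces `n_frontal` frontal-like followed by `n_lateral` lateral-like
#' phantoms sharing `base_spec`'s resolution, noise and jitter settings.
#' Per-sample seeds are derived deterministically from `seed` (a fixed affine
#' counter scheme), so the dataset is reproducible element-wise and label
#' counts never depend on the seed.
#'
#' @param n_frontal,n_lateral Non-negative sample counts.
#' @param base_spec A [phantom_spec()] supplying resolution, noise and jitter.
#' @param seed Integer master seed.
#' @return A tibble with columns `id`, `label`, `seed`, and `pixels`
#'   (list-column of matrices).
#' @export
generate_dataset <- function(n_frontal, n_lateral, base_spec, seed = 0L) {
  check_number(n_frontal, "n_frontal", lower = 0, integerish = TRUE)
  check_number(n_lateral, "n_lateral", lower = 0, integerish = TRUE)
  if (!inherits(base_spec, "phantom_spec"))
    abort_field("base_spec", "must be a phantom_spec")
  n <- n_frontal + n_lateral
  labels <- rep(c("FRONTAL", "LATERAL"), c(n_frontal, n_lateral))
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, i), integer(1))
  pixels <- lapply(seq_len(n), function(i) {
    sp <- phantom_spec(labels[i], base_spec$resolution, base_spec$noise_sigma,
                       base_spec$jitter, seeds[i])
    generate_phantom(sp)$pixels
  })
  tibble::tibble(id = seq_len(n), label = labels, seed = seeds,
                 pixels = pixels)
}
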