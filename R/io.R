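# Grayscale image I/O. On disk images are 8-bit grayscale PNG in [0, 255];
# internally pixels live on [-1, 1] (the generator's Tanh range). The affine
# map between the two is exact at both endpoints and round-trips to within
# one quantisation step (1/255 on the disk scale, 2/255 internally).

internal_to_disk <- function(px) {
  # [-1, 1] -> {0, ..., 255}, rounding half away from zero
  floor((px + 1) / 2 * 255 + 0.5)
}

disk_to_internal <- function(v) v / 255 * 2 - 1

# Bilinear resample of a matrix to side x side (align-corners-free convention:
# samples at pixel centres, clamped at the borders).
resize_bilinear <- function(m, side) {
  H <- nrow(m)
  W <- ncol(m)
  if (H == side && W == side) return(m)
  map <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    s <- pmin(pmax(s, 0), n_in - 1)
    i0 <- floor(s)
    list(i0 = pmin(i0, n_in - 2) + 1, f = s - pmin(i0, n_in - 2))
  }
  if (H == 1L || W == 1L) {
    # degenerate input: nearest neighbour
    ri <- pmin(pmax(round((seq_len(side) - 0.5) * H / side + 0.5), 1), H)
    ci <- pmin(pmax(round((seq_len(side) - 0.5) * W / side + 0.5), 1), W)
    return(m[ri, ci, drop = FALSE])
  }
  r <- map(side, H)
  cc <- map(side, W)
  m00 <- m[r$i0, cc$i0, drop = FALSE]
  m10 <- m[r$i0 + 1, cc$i0, drop = FALSE]
  m01 <- m[r$i0, cc$i0 + 1, drop = FALSE]
  m11 <- m[r$i0 + 1, cc$i0 + 1, drop = FALSE]
  fr <- matrix(r$f, side, side)
  fc <- matrix(cc$f, side, side, byrow = TRUE)
  m00 * (1 - fr) * (1 - fc) + m10 * fr * (1 - fc) +
    m01 * (1 - fr) * fc + m11 * fr * fc
}

#' Load a grayscale image
#'
#' Reads a PNG (color images are collapsed to grayscale by channel mean),
#' rescales intensities from the 8-bit disk range to the internal \[-1, 1\]
#' range, and resizes to `resolution` by bilinear interpolation.
#'
#' @param path Path to a PNG file.
#' @param resolution Target square side in pixels.
#' @return An [image_sample()] with label `"UNKNOWN"`.
#' @export
load_image <- function(path, resolution = 64L) {
  check_number(resolution, "resolution", lower = 1, integerish = TRUE)
  if (!file.exists(path))
    stop(sprintf("cannot read image: '%s' does not exist", path), call. = FALSE)
  img <- tryCatch(png::readPNG(path),
                  error = function(e)
                    stop(sprintf("cannot decode '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE))
  if (length(dim(img)) == 3L) {
    nch <- dim(img)[3]
    gray <- if (nch >= 3L) (img[, , 1] + img[, , 2] + img[, , 3]) / 3
            else img[, , 1]
  } else {
    gray <- img
  }
  if (length(gray) == 0L)
    stop(sprintf("zero-sized image: '%s'", path), call. = FALSE)
  px <- resize_bilinear(gray * 2 - 1, resolution)
  image_sample(pmin(pmax(px, -1), 1), "UNKNOWN")
}

#' Save an image sample as 8-bit grayscale PNG
#'
#' @param sample An [image_sample()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_image <- function(sample, path) {
  if (!is_image_sample(sample)) sample <- image_sample(sample)
  v <- internal_to_disk(sample$pixels) / 255
  ok <- tryCatch({
    png::writePNG(v, target = path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    stop(sprintf("cannot write image to '%s'", path), call. = FALSE)
  invisible(path)
}
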