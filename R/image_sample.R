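#' Construct an image sample
#'
#' The unit of data flowing through the pipeline: one square grayscale image
#' with pixel values on the internal \[-1, 1\] scale (matching the generator's
#' Tanh output range) and an optional view label.
#'
#' @param pixels Square numeric matrix with all values in \[-1, 1\].
#' @param label One of `"FRONTAL"`, `"LATERAL"`, `"UNKNOWN"`.
#' @return An object of class `image_sample`: a list with elements `pixels`
#'   (matrix) and `label` (character scalar).
#' @export
image_sample <- function(pixels, label = "UNKNOWN") {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    abort_field("pixels", "must be a numeric matrix")
  if (nrow(pixels) != ncol(pixels))
    abort_field("pixels", "must be square")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    abort_field("pixels", "must be finite")
  if (min(pixels) < -1 || max(pixels) > 1)
    abort_field("pixels", "values must lie in [-1, 1]")
  label <- match.arg(label, c("FRONTAL", "LATERAL", "UNKNOWN"))
  structure(list(pixels = pixels, label = label), class = "image_sample")
}

#' @export
print.image_sample <- function(x, ...) {
  cat(sprintf("<image_sample> %dx%d, label %s, range [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), x$label,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

is_image_sample <- function(x) inherits(x, "image_sample")

# Accepts an image_sample, a matrix, a list of either, or a dataset tibble
# with a `pixels` list-column; returns an (H, W, 1, N) array.
as_image_batch <- function(x) {
  pix <- if (is_image_sample(x)) {
    list(x$pixels)
  } else if (is.matrix(x)) {
    list(x)
  } else if (is.data.frame(x)) {
    x$pixels
  } else if (is.list(x)) {
    lapply(x, function(s) if (is_image_sample(s)) s$pixels else s)
  } else {
    stop("cannot interpret input as image batch", call. = FALSE)
  }
  if (length(pix) == 0L) stop("empty image batch", call. = FALSE)
  H <- nrow(pix[[1L]])
  W <- ncol(pix[[1L]])
  ok <- vapply(pix, function(p) nrow(p) == H && ncol(p) == W, logical(1))
  if (!all(ok)) stop("images have mismatched resolutions", call. = FALSE)
  array(unlist(pix, use.names = FALSE), c(H, W, 1L, length(pix)))
}
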