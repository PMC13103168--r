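# Classical comparator methods: a Canny-edge score and a histogram-intersection
# score, each turned into a detector by an F1-maximising threshold grid search.

#' Canny edge-fraction score
#'
#' Applies the full classical Canny operator (Gaussian smoothing, Sobel
#' gradient, non-maximum suppression, double-threshold hysteresis) and
#' returns the fraction of pixels marked as edges, in \[0, 1\]. Constant
#' images score 0. Frontal-like and lateral-like images differ systematically
#' in edge content, which is what the baseline exploits.
#'
#' @param image An [image_sample()] or pixel matrix.
#' @param sigma Gaussian smoothing standard deviation (pixels).
#' @param low,high Hysteresis thresholds on the Sobel gradient magnitude
#'   (`low < high`).
#' @return Edge-pixel fraction in \[0, 1\].
#' @export
canny_score <- function(image, sigma = 1, low = 0.1, high = 0.3) {
  m <- if (is_image_sample(image)) image$pixels else image
  check_number(sigma, "sigma", lower = 1e-12)
  if (!(low < high)) abort_field("low", "must satisfy low < high")
  mean(canny_edges(m, sigma, low, high))
}

#' Reference intensity histogram of the in-distribution class
#'
#' Mean of per-image normalised histograms over `n_bins` equal-width bins on
#' \[-1, 1\].
#'
#' @param id_images Dataset tibble (with `pixels` list-column) or list of
#'   images; must be non-empty.
#' @param n_bins Number of histogram bins (default 32).
#' @return An object of class `reference_histogram`: list with `bin_edges`
#'   (length `n_bins + 1`) and `mean_density` (sums to 1).
#' @export
fit_reference_histogram <- function(id_images, n_bins = 32L) {
  check_number(n_bins, "n_bins", lower = 1, integerish = TRUE)
  pix <- if (is.data.frame(id_images)) id_images$pixels else id_images
  if (length(pix) == 0L) abort_field("id_images", "must be non-empty")
  edges <- seq(-1, 1, length.out = n_bins + 1L)
  dens <- vapply(pix, function(p) {
    m <- if (is_image_sample(p)) p$pixels else p
    image_histogram(m, edges)
  }, numeric(n_bins))
  md <- if (is.matrix(dens)) rowMeans(dens) else dens
  structure(list(bin_edges = edges, mean_density = md / sum(md)),
            class = "reference_histogram")
}

# Normalised counts on fixed bin edges; bins are [e_i, e_{i+1}), the last
# closed, values clamped into range.
image_histogram <- function(m, edges) {
  idx <- findInterval(as.vector(m), edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  tabulate(idx, nbins = length(edges) - 1L) / length(m)
}

#' Histogram-intersection score against the reference
#'
#' Similarity \eqn{\sum_i \min(h_{image,i}, h_{ref,i})} in \[0, 1\]; higher
#' means more in-distribution-like.
#'
#' @param image An [image_sample()] or pixel matrix.
#' @param ref A [fit_reference_histogram()] result.
#' @return Intersection value in \[0, 1\].
#' @export
histogram_score <- function(image, ref) {
  if (!inherits(ref, "reference_histogram"))
    abort_field("ref", "must be a reference_histogram")
  m <- if (is_image_sample(image)) image$pixels else image
  h <- image_histogram(m, ref$bin_edges)
  sum(pmin(h, ref$mean_density))
}

#' F1-maximising threshold grid search
#'
#' Scans a threshold grid for the value maximising the F1 score of the
#' OOD-positive classification. Ties are broken toward higher precision, then
#' toward the smaller threshold.
#'
#' @param scores Numeric scores, one per sample.
#' @param labels Logical, `TRUE` for OOD samples; both classes must be
#'   present.
#' @param grid Non-empty numeric vector of candidate thresholds.
#' @param ood_side `"ABOVE"` (OOD when score > threshold) or `"BELOW"`
#'   (OOD when score < threshold).
#' @return One-row tibble: `threshold`, `f1`, `accuracy`, `precision`,
#'   `recall`.
#' @export
grid_search_threshold <- function(scores, labels, grid,
                                  ood_side = c("BELOW", "ABOVE")) {
  ood_side <- match.arg(ood_side)
  if (length(scores) != length(labels))
    abort_field("labels", "must match scores in length")
  if (length(grid) == 0L) abort_field("grid", "must be non-empty")
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    abort_field("labels", "both classes must be present")
  best <- NULL
  for (thr in grid) {
    pred <- if (ood_side == "ABOVE") scores > thr else scores < thr
    mr <- metrics_from_confusion(confusion_matrix(labels, pred))
    cand <- list(threshold = thr, m = mr)
    if (is.null(best) ||
        mr$f1 > best$m$f1 ||
        (mr$f1 == best$m$f1 && mr$precision > best$m$precision) ||
        (mr$f1 == best$m$f1 && mr$precision == best$m$precision &&
         thr < best$threshold)) {
      best <- cand
    }
  }
  tibble::tibble(threshold = best$threshold, f1 = best$m$f1,
                 accuracy = best$m$accuracy, precision = best$m$precision,
                 recall = best$m$recall)
}

#' Score a dataset with a baseline method
#'
#' @param data Dataset tibble with a `pixels` list-column.
#' @param method `"CANNY"` or `"HISTOGRAM"`.
#' @param ref Reference histogram (required for `"HISTOGRAM"`).
#' @param sigma,low,high Canny parameters.
#' @return Tibble `id`, `label`, `score`.
#' @export
baseline_scores <- function(data, method = c("CANNY", "HISTOGRAM"),
                            ref = NULL, sigma = 1, low = 0.1, high = 0.3) {
  method <- match.arg(method)
  score <- vapply(data$pixels, function(p) {
    if (method == "CANNY") canny_score(p, sigma, low, high)
    else histogram_score(p, ref)
  }, numeric(1))
  tibble::tibble(id = data$id %||% seq_along(score),
                 label = data$label %||% rep("UNKNOWN", length(score)),
                 score = score)
}

#' Calibrate and evaluate a classical baseline
#'
#' Scores the calibration split, grid-searches the F1-maximising threshold on
#' it (both classes must be present), then applies the frozen threshold to
#' the test split. For both methods the OOD side is `"BELOW"`: lateral-like
#' images intersect the frontal reference histogram less, and carry less
#' Canny edge structure, than frontal-like ones.
#'
#' @param calibration,test Dataset tibbles with `pixels` and `label` columns.
#' @param method `"CANNY"` or `"HISTOGRAM"`.
#' @param id_label Label of the in-distribution class.
#' @param n_grid Number of grid points spanning the calibration score range.
#' @param ... Passed to [baseline_scores()] (`sigma`, `low`, `high`,
#'   `n_bins` via `ref`).
#' @return One-row tibble: `method`, `threshold`, `accuracy`, `precision`,
#'   `recall`, `f1`.
#' @export
evaluate_baseline <- function(calibration, test,
                              method = c("CANNY", "HISTOGRAM"),
                              id_label = "FRONTAL", n_grid = 101L, ...) {
  method <- match.arg(method)
  dots <- list(...)
  ref <- NULL
  if (method == "HISTOGRAM") {
    id_rows <- calibration[calibration$label == id_label, , drop = FALSE]
    ref <- fit_reference_histogram(id_rows, n_bins = dots$n_bins %||% 32L)
  }
  args <- dots[names(dots) %in% c("sigma", "low", "high")]
  sc_cal <- do.call(baseline_scores,
                    c(list(calibration, method, ref = ref), args))
  rng <- range(sc_cal$score)
  grid <- seq(rng[1], rng[2], length.out = n_grid)
  gs <- grid_search_threshold(sc_cal$score, sc_cal$label != id_label, grid,
                              ood_side = "BELOW")
  sc_test <- do.call(baseline_scores, c(list(test, method, ref = ref), args))
  pred <- sc_test$score < gs$threshold
  mr <- metrics_from_confusion(confusion_matrix(sc_test$label != id_label,
                                                pred))
  tibble::tibble(method = method, threshold = gs$threshold,
                 accuracy = mr$accuracy, precision = mr$precision,
                 recall = mr$recall, f1 = mr$f1)
}
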