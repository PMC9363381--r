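#' Three-class global Otsu threshold with middle class as background
#'
#' Computes the pair of thresholds `(t_low, t_high)` that maximises the
#' between-class variance of a three-way partition of the image histogram
#' (256 bins over the intensity range). Following the thresholding convention
#' used for speckle counting, the middle class is assigned to background, so
#' the foreground is only the top class: pixels strictly above `t_high`.
#'
#' The search is exhaustive over all threshold pairs on the binned histogram
#' (vectorised with cumulative sums), so the result is the exact maximiser;
#' ties are broken towards the lowest `(t_low, t_high)` pair.
#'
#' @param image numeric matrix (one channel) with at least three distinct
#'   values.
#' @param levels number of histogram bins (default 256).
#' @return an object of class `threshold_result`: a list with `t_low`,
#'   `t_high`, `applied_min_threshold` (NULL until a per-replicate floor is
#'   applied), `method`, and the bin indices `bin_low`, `bin_high`.
#' @seealso [calibrate_min_threshold()], [apply_threshold()]
#' @export
otsu_three_class <- function(image, levels = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 3L) {
    abort("image has fewer than 3 distinct intensity values; three-class thresholding is degenerate.",
          class = "gs_degenerate_input")
  }
  lo <- min(x); hi <- max(x)
  width <- (hi - lo) / levels
  # bin k covers (lo + (k-1) w, lo + k w]; lowest value goes to bin 1
  bin <- pmin(pmax(ceiling((x - lo) / width), 1L), levels)
  counts <- tabulate(bin, nbins = levels)
  p <- counts / sum(counts)
  mids <- lo + (seq_len(levels) - 0.5) * width
  cw <- cumsum(p)            # cumulative weight up to bin k
  cm <- cumsum(p * mids)     # cumulative weighted mean numerator

  # between-class variance for classes [1..i], [i+1..j], [j+1..K], i < j.
  # BCV = sum_k w_k mu_k^2 - mu_T^2 (constant offset dropped for the argmax)
  i <- seq_len(levels - 2L)
  w1 <- cw[i]; m1 <- cm[i]
  term1 <- ifelse(w1 > 0, m1^2 / w1, 0)
  # matrix over (i, j): rows i, cols j
  j <- seq(2L, levels - 1L)
  w2 <- outer(rep(1, length(i)), cw[j]) - outer(cw[i], rep(1, length(j)))
  m2 <- outer(rep(1, length(i)), cm[j]) - outer(cm[i], rep(1, length(j)))
  w3 <- 1 - outer(rep(1, length(i)), cw[j])
  m3 <- cm[levels] - outer(rep(1, length(i)), cm[j])
  bcv <- term1 + ifelse(w2 > 0, m2^2 / w2, 0) + ifelse(w3 > 0, m3^2 / w3, 0)
  bcv[outer(i, j, ">=")] <- -Inf
  # all three classes must be populated
  empty <- outer(cw[i] == 0, rep(TRUE, length(j))) | w2 == 0 | w3 == 0
  bcv[empty] <- -Inf
  if (!any(is.finite(bcv))) {
    abort("no three-way partition with non-empty classes exists.",
          class = "gs_degenerate_input")
  }
  # lexicographic tie-break: smallest i, then smallest j
  best <- which(bcv == max(bcv), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2])[1], ]
  bi <- i[best[1]]; bj <- j[best[2]]
  structure(
    list(t_low = lo + bi * width, t_high = lo + bj * width,
         applied_min_threshold = NULL, method = sprintf("otsu3-%dbin", levels),
         bin_low = bi, bin_high = bj),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s: t_low = %.4g, t_high = %.4g%s\n",
              x$method, x$t_low, x$t_high,
              if (!is.null(x$applied_min_threshold))
                sprintf(", floor = %.4g", x$applied_min_threshold) else ""))
  invisible(x)
}

#' Per-replicate minimum-threshold calibration
#'
#' The speckle-counting threshold floor for one replicate is calibrated on the
#' replicate's reference images (in the study design: arsenite-treated
#' non-induced cells). Each reference image is thresholded with
#' [otsu_three_class()] and the floor is the median of their upper thresholds
#' `t_high`; all images of the replicate are then thresholded at no less than
#' this floor.
#'
#' @param reference_images list of single-channel matrices (or
#'   [micrograph()]s, in which case `stain` selects the channel).
#' @param stain stain to extract when micrographs are supplied.
#' @return the calibrated minimum threshold (single number).
#' @export
calibrate_min_threshold <- function(reference_images, stain = NULL) {
  if (length(reference_images) == 0L) {
    abort(paste("no reference images supplied; check that the manifest's",
                "reference condition is present for this replicate."),
          class = "gs_empty_reference")
  }
  t_highs <- vapply(reference_images, function(img) {
    if (inherits(img, "micrograph")) img <- get_channel(img, stain)
    otsu_three_class(img)$t_high
  }, numeric(1))
  median(t_highs)
}

#' Apply a three-class threshold (with optional floor) to an image
#'
#' Foreground is the top Otsu class: pixels strictly above
#' `max(t_high, floor)`. Raising the floor can only shrink the foreground.
#'
#' @param image numeric matrix.
#' @param threshold a `threshold_result` from [otsu_three_class()].
#' @param floor optional per-replicate minimum threshold from
#'   [calibrate_min_threshold()].
#' @return list with `foreground` (logical matrix), `applied` (the threshold
#'   actually used) and the updated `threshold_result`.
#' @export
apply_threshold <- function(image, threshold, floor = NULL) {
  applied <- if (is.null(floor)) threshold$t_high else max(threshold$t_high, floor)
  threshold$applied_min_threshold <- floor
  list(foreground = image > applied, applied = applied, threshold = threshold)
}
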