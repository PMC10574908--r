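#' Region-of-interest specification for CNR
#'
#' Rectangles are given as `c(row, col, height, width)` (top-left corner,
#' 1-based). Several target/background pairs may be supplied; [cnr()] then
#' averages the per-pair scores.
#'
#' @param target A rectangle or list of rectangles.
#' @param background A rectangle or list of rectangles (recycled against
#'   `target` if shorter).
#' @return An `roi_spec` object.
#' @export
roi_spec <- function(target, background) {
  as_rect_list <- function(r) {
    if (is.numeric(r)) r <- list(r)
    lapply(r, function(rr) {
      if (length(rr) != 4 || any(rr[3:4] < 1))
        stop_invalid("each ROI must be c(row, col, height, width) with positive size")
      as.integer(rr)
    })
  }
  structure(list(target = as_rect_list(target),
                 background = as_rect_list(background)),
            class = "roi_spec")
}

extract_roi <- function(img, rect) {
  r2 <- rect[1] + rect[3] - 1L
  c2 <- rect[2] + rect[4] - 1L
  if (rect[1] < 1 || rect[2] < 1 || r2 > nrow(img) || c2 > ncol(img))
    stop_invalid("ROI lies outside the image")
  img[rect[1]:r2, rect[2]:c2]
}

rects_overlap <- function(a, b) {
  !(a[1] + a[3] - 1 < b[1] || b[1] + b[3] - 1 < a[1] ||
    a[2] + a[4] - 1 < b[2] || b[2] + b[4] - 1 < a[2])
}

#' Contrast-to-noise ratio
#'
#' `(mu_T - mu_B) / sqrt(sd_T^2 + sd_B^2)` between a target and a background
#' region; with several target/background pairs the per-pair CNRs are
#' averaged. Quantifies how distinguishable a feature is from the background
#' given the local noise.
#'
#' @param img Numeric matrix.
#' @param rois An [roi_spec()].
#' @return Mean CNR (dimensionless).
#' @export
cnr <- function(img, rois) {
  assert_image(img, "img")
  if (!inherits(rois, "roi_spec")) stop_invalid("rois must be an roi_spec")
  n <- length(rois$target)
  bg <- rep(rois$background, length.out = n)
  scores <- vapply(seq_len(n), function(i) {
    if (rects_overlap(rois$target[[i]], bg[[i]]))
      stop_invalid("target and background ROIs must be disjoint")
    tv <- extract_roi(img, rois$target[[i]])
    bv <- extract_roi(img, bg[[i]])
    denom <- sqrt(stats::var(as.vector(tv)) + stats::var(as.vector(bv)))
    if (denom < 1e-12) stop_invalid("undefined CNR: zero variance in both ROIs")
    (mean(tv) - mean(bv)) / denom
  }, numeric(1))
  mean(scores)
}

edge_kernels <- list(
  sobel   = matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3),
  prewitt = matrix(c(-1, -1, -1, 0, 0, 0, 1, 1, 1), 3, 3),
  scharr  = matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, 3) / 16
)

#' Gradient magnitude sharpness measure
#'
#' Per-pixel `sqrt((I * f_h)^2 + (I * f_v)^2)` under a named pair of
#' horizontal/vertical edge operators, and its image mean as the scalar
#' sharpness score: blurring an image lowers the score, restoring detail
#' raises it.
#'
#' @param img Numeric matrix.
#' @param operator One of `"sobel"`, `"prewitt"`, `"scharr"`.
#' @return List with the gradient `map` and the scalar mean `score`.
#' @export
gradient_magnitude <- function(img, operator = "sobel") {
  assert_image(img, "img")
  if (!operator %in% names(edge_kernels))
    stop_invalid(sprintf("unknown edge operator '%s'", operator))
  fh <- edge_kernels[[operator]]
  gx <- convolve_replicate(img, fh)
  gy <- convolve_replicate(img, t(fh))
  map <- sqrt(gx^2 + gy^2)
  list(map = map, score = mean(map))
}
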