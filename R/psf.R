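#' Gaussian point-spread-function kernel
#'
#' Builds the isotropic 2D Gaussian PSF used throughout the package: the
#' detector's response to a point source, parameterized by a single width
#' `sigma` in pixels. The continuous profile is sampled at integer pixel
#' offsets, truncated at `truncation_multiple * sigma`, and renormalized to
#' unit sum so convolution conserves flux.
#'
#' @param sigma Blur width in pixels; must be positive.
#' @param truncation_multiple Kernel support half-width as a multiple of
#'   `sigma` (default 4; the discarded tail mass is below 1e-4).
#' @return An object of class `gaussian_psf`: a list with `sigma`,
#'   `support_halfwidth` and the normalized `kernel` matrix of odd side
#'   `2 * support_halfwidth + 1`.
#' @examples
#' psf <- gaussian_psf_kernel(2.61)
#' dim(psf$kernel)  # 23 x 23
#' sum(psf$kernel)  # 1
#' @export
gaussian_psf_kernel <- function(sigma, truncation_multiple = 4) {
  assert_positive_scalar(sigma, "sigma")
  if (!is.numeric(truncation_multiple) || truncation_multiple < 2)
    stop_invalid("truncation_multiple must be >= 2")
  h <- as.integer(ceiling(truncation_multiple * sigma))
  offsets <- seq(-h, h)
  g1 <- exp(-offsets^2 / (2 * sigma^2))
  kernel <- outer(g1, g1)
  kernel <- kernel / sum(kernel)
  structure(
    list(sigma = sigma, support_halfwidth = h, kernel = kernel),
    class = "gaussian_psf"
  )
}

#' @export
print.gaussian_psf <- function(x, ...) {
  cat(sprintf("Gaussian PSF: sigma = %.4g px, kernel %d x %d\n",
              x$sigma, nrow(x$kernel), ncol(x$kernel)))
  invisible(x)
}

# Accept either a gaussian_psf or a bare kernel matrix; returns the matrix.
as_psf_kernel <- function(psf, require_normalized = TRUE) {
  kernel <- if (inherits(psf, "gaussian_psf")) psf$kernel else psf
  if (!is.matrix(kernel) || !is.numeric(kernel))
    stop_invalid("psf must be a gaussian_psf or a numeric kernel matrix")
  if (require_normalized && abs(sum(kernel) - 1) > 1e-8)
    stop_invalid("psf kernel must be normalized to unit sum")
  kernel
}

#' Gaussian MTF model
#'
#' Modulation transfer function of the Gaussian line-spread function: the
#' continuous Fourier transform of a Gaussian of width `sigma` px, giving
#' `exp(-2 * pi^2 * sigma^2 * u^2)` at spatial frequency `u` cycles/pixel.
#'
#' @param sigma LSF width in pixels.
#' @param frequencies Nonnegative, strictly increasing frequency grid in
#'   cycles/pixel.
#' @param pixel_pitch_mm Optional pixel pitch; when given, an `lp_per_mm`
#'   column is added (`u / pitch`).
#' @return A tibble of class `mtf_curve` with columns `frequency` and `mtf`.
#' @export
mtf_from_sigma <- function(sigma, frequencies = seq(0, 0.5, by = 0.01),
                           pixel_pitch_mm = NULL) {
  assert_positive_scalar(sigma, "sigma")
  if (any(frequencies < 0)) stop_invalid("frequencies must be nonnegative")
  if (is.unsorted(frequencies, strictly = TRUE))
    stop_invalid("frequencies must be strictly increasing")
  out <- tibble::tibble(
    frequency = frequencies,
    mtf = exp(-2 * pi^2 * sigma^2 * frequencies^2)
  )
  if (!is.null(pixel_pitch_mm)) out$lp_per_mm <- frequencies / pixel_pitch_mm
  class(out) <- c("mtf_curve", class(out))
  attr(out, "sigma") <- sigma
  out
}

#' Recover the LSF width from a measured MTF curve
#'
#' Least-squares fit of the Gaussian MTF model. Because the model is
#' `exp(-2 pi^2 sigma^2 u^2)`, the fit is performed in the log domain where it
#' is linear in `u^2`; values below `min_mtf` are excluded to keep the noisy
#' tail from dominating.
#'
#' @param curve A data frame with columns `frequency` (cycles/pixel) and
#'   `mtf`, e.g. from [mtf_from_sigma()] or a 2-column CSV read with
#'   [read_mtf_csv()].
#' @param min_mtf Modulation floor for inclusion in the fit (default 0.01).
#' @return Fitted `sigma` in pixels.
#' @export
sigma_from_mtf_fit <- function(curve, min_mtf = 0.01) {
  u <- curve$frequency
  v <- curve$mtf
  keep <- is.finite(v) & v > min_mtf & u > 0
  if (sum(keep) < 2)
    stop_invalid("too few usable MTF samples for a fit")
  if (stats::sd(v[keep]) < 1e-12)
    stop_invalid("degenerate MTF curve: all values constant")
  # log(MTF) = -2 pi^2 sigma^2 u^2 : slope through the origin in u^2
  x <- u[keep]^2
  y <- log(v[keep])
  slope <- sum(x * y) / sum(x * x)
  if (slope >= 0)
    stop_invalid("degenerate MTF curve: no decay with frequency")
  sqrt(-slope / (2 * pi^2))
}

#' Read / write 2-column curve CSVs (frequency,value or position,value)
#' @param path File path.
#' @return `read_mtf_csv` returns a tibble with `frequency` and `mtf`.
#' @export
read_mtf_csv <- function(path) {
  df <- utils::read.csv(path)
  tibble::tibble(frequency = df[[1]], mtf = df[[2]])
}

#' @rdname read_mtf_csv
#' @param curve Curve data frame.
#' @export
write_mtf_csv <- function(curve, path) {
  utils::write.csv(
    data.frame(frequency = curve$frequency, mtf = curve$mtf),
    path, row.names = FALSE
  )
  invisible(path)
}
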