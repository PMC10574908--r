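#' SSIM configuration
#'
#' Parameters of the structural similarity index: stabilization fractions
#' `k1`, `k2`, the dynamic range `L` of the data (ADU full scale; 4095 for
#' the 12-bit detector profiles, or 1 for unit-normalized images), the local
#' statistics window, and the component exponents.
#'
#' @param k1,k2 Stabilization fractions (defaults 0.01 and 0.03).
#' @param dynamic_range Data full scale `L` (default 4095).
#' @param window_size Side of the local window (odd; default 11).
#' @param window_sigma Gaussian taper of the window (default 1.5).
#' @param alpha,beta,gamma Exponents of the luminance, contrast and
#'   structure terms (defaults 1).
#' @return An `ssim_config` list.
#' @export
ssim_config <- function(k1 = 0.01, k2 = 0.03, dynamic_range = 4095,
                        window_size = 11, window_sigma = 1.5,
                        alpha = 1, beta = 1, gamma = 1) {
  if (k1 <= 0 || k2 <= 0) stop_invalid("k1 and k2 must be positive")
  assert_positive_scalar(dynamic_range, "dynamic_range")
  if (window_size %% 2 != 1) stop_invalid("window_size must be odd")
  structure(list(k1 = k1, k2 = k2, dynamic_range = dynamic_range,
                 window_size = window_size, window_sigma = window_sigma,
                 alpha = alpha, beta = beta, gamma = gamma),
            class = "ssim_config")
}

gaussian_window <- function(size, sigma) {
  h <- (size - 1) / 2
  g <- exp(-(seq(-h, h))^2 / (2 * sigma^2))
  w <- outer(g, g)
  w / sum(w)
}

#' Structural similarity index (SSIM)
#'
#' Windowed full-reference similarity combining luminance, contrast and
#' structure comparisons. Local means, variances and covariance are computed
#' under a Gaussian-tapered window and combined as
#' `l^alpha * c^beta * s^gamma`; with the default exponents and the
#' `C3 = C2/2` convention this reduces to the familiar two-factor form. The
#' score is the mean of the local SSIM map.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param cfg An [ssim_config()].
#' @param return_map If `TRUE`, also return the local SSIM map.
#' @return The mean SSIM score in `[-1, 1]` (or a list with `score` and
#'   `map` when `return_map = TRUE`).
#' @export
ssim <- function(x, y, cfg = ssim_config(), return_map = FALSE) {
  assert_image(x, "x"); assert_image(y, "y")
  assert_same_shape(x, y)
  w <- gaussian_window(cfg$window_size, cfg$window_sigma)
  C1 <- (cfg$k1 * cfg$dynamic_range)^2
  C2 <- (cfg$k2 * cfg$dynamic_range)^2
  C3 <- C2 / 2

  mu_x <- convolve_replicate(x, w)
  mu_y <- convolve_replicate(y, w)
  var_x <- pmax(convolve_replicate(x * x, w) - mu_x^2, 0)
  var_y <- pmax(convolve_replicate(y * y, w) - mu_y^2, 0)
  cov_xy <- convolve_replicate(x * y, w) - mu_x * mu_y
  sd_x <- sqrt(var_x)
  sd_y <- sqrt(var_y)

  l <- (2 * mu_x * mu_y + C1) / (mu_x^2 + mu_y^2 + C1)
  cc <- (2 * sd_x * sd_y + C2) / (var_x + var_y + C2)
  s <- (cov_xy + C3) / (sd_x * sd_y + C3)
  map <- sign(l)^cfg$alpha * abs(l)^cfg$alpha *
    cc^cfg$beta * sign(s)^cfg$gamma * abs(s)^cfg$gamma
  score <- mean(map)
  if (return_map) list(score = score, map = map) else score
}
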