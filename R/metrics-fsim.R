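#' FSIM configuration
#'
#' Constants of the feature similarity index and its log-Gabor filter bank.
#' `t1` stabilizes the phase-congruency comparison, `t2` the
#' gradient-magnitude comparison (both on inputs rescaled to the 8-bit
#' range). The filter bank follows the metric's canonical form: 4 scales,
#' 4 orientations, minimum wavelength 6 px, scale multiplier 2, radial
#' bandwidth parameter 0.55.
#'
#' @param t1,t2 Stability constants (defaults 0.85 and 160).
#' @param alpha,beta Exponents balancing the PC and GM terms (defaults 1).
#' @param n_scales,n_orientations Log-Gabor bank size.
#' @param min_wavelength Finest filter wavelength in pixels.
#' @param scale_multiplier Wavelength ratio between successive scales.
#' @param sigma_f Ratio defining the radial log-Gaussian bandwidth.
#' @return An `fsim_config` list.
#' @export
fsim_config <- function(t1 = 0.85, t2 = 160, alpha = 1, beta = 1,
                        n_scales = 4, n_orientations = 4,
                        min_wavelength = 6, scale_multiplier = 2,
                        sigma_f = 0.55) {
  if (t1 <= 0 || t2 <= 0) stop_invalid("t1 and t2 must be positive")
  structure(list(t1 = t1, t2 = t2, alpha = alpha, beta = beta,
                 n_scales = n_scales, n_orientations = n_orientations,
                 min_wavelength = min_wavelength,
                 scale_multiplier = scale_multiplier, sigma_f = sigma_f),
            class = "fsim_config")
}

# Frequency-plane coordinates with DC at element [1,1] (ifftshift layout).
freq_grid <- function(n) {
  v <- (seq_len(n) - 1 - floor(n / 2)) / n
  shift <- floor(n / 2)
  v[((seq_len(n) - 1 + shift) %% n) + 1]
}

# Log-Gabor x angular-spread filter bank in the frequency domain.
log_gabor_bank <- function(dim_img, cfg) {
  n1 <- dim_img[1]; n2 <- dim_img[2]
  uy <- matrix(freq_grid(n1), n1, n2)
  ux <- matrix(freq_grid(n2), n1, n2, byrow = TRUE)
  radius <- sqrt(ux^2 + uy^2)
  radius[1, 1] <- 1
  theta <- atan2(-uy, ux)
  lowpass <- 1 / (1 + (radius / 0.45)^30)
  sin_t <- sin(theta); cos_t <- cos(theta)
  theta_sigma <- pi / cfg$n_orientations / 1.2

  radial <- lapply(seq_len(cfg$n_scales), function(s) {
    wavelength <- cfg$min_wavelength * cfg$scale_multiplier^(s - 1)
    f0 <- 1 / wavelength
    lg <- exp(-(log(radius / f0))^2 / (2 * log(cfg$sigma_f)^2)) * lowpass
    lg[1, 1] <- 0
    lg
  })
  angular <- lapply(seq_len(cfg$n_orientations), function(o) {
    angle <- (o - 1) * pi / cfg$n_orientations
    ds <- sin_t * cos(angle) - cos_t * sin(angle)
    dc <- cos_t * cos(angle) + sin_t * sin(angle)
    dtheta <- abs(atan2(ds, dc))
    exp(-dtheta^2 / (2 * theta_sigma^2))
  })
  list(radial = radial, angular = angular)
}

#' Phase congruency map
#'
#' Contrast-invariant measure of local phase alignment across scales,
#' computed from a log-Gabor quadrature filter bank: per orientation, the
#' phase-aligned energy of the scale responses divided by the total response
#' amplitude. High values mark edges and lines regardless of their contrast;
#' a constant image yields a near-zero map. The normalization floor is
#' proportional to the mean response amplitude, so scaling the image
#' intensities (or adding an offset) leaves the map unchanged.
#'
#' @param x Numeric matrix.
#' @param cfg An [fsim_config()] describing the filter bank.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
phase_congruency_map <- function(x, cfg = fsim_config()) {
  assert_image(x, "x")
  # even (mirror) extension: the periodic FFT then sees no artificial
  # discontinuity at the image frame, so borders are not spurious edges
  n1 <- nrow(x); n2 <- ncol(x)
  x <- rbind(x, x[n1:1, , drop = FALSE])
  x <- cbind(x, x[, n2:1, drop = FALSE])
  bank <- log_gabor_bank(dim(x), cfg)
  XF <- fft2(x)
  total_energy <- matrix(0, nrow(x), ncol(x))
  total_an <- matrix(0, nrow(x), ncol(x))
  for (o in seq_len(cfg$n_orientations)) {
    sum_re <- matrix(0, nrow(x), ncol(x))
    sum_im <- matrix(0, nrow(x), ncol(x))
    sum_an <- matrix(0, nrow(x), ncol(x))
    re_s <- vector("list", cfg$n_scales)
    im_s <- vector("list", cfg$n_scales)
    for (s in seq_len(cfg$n_scales)) {
      eo <- ifft2(XF * (bank$radial[[s]] * bank$angular[[o]]))
      re_s[[s]] <- Re(eo); im_s[[s]] <- Im(eo)
      sum_re <- sum_re + re_s[[s]]
      sum_im <- sum_im + im_s[[s]]
      sum_an <- sum_an + Mod(eo)
    }
    xe <- sqrt(sum_re^2 + sum_im^2) + 1e-12
    mean_cos <- sum_re / xe
    mean_sin <- sum_im / xe
    energy <- matrix(0, nrow(x), ncol(x))
    for (s in seq_len(cfg$n_scales)) {
      energy <- energy + re_s[[s]] * mean_cos + im_s[[s]] * mean_sin -
        abs(re_s[[s]] * mean_sin - im_s[[s]] * mean_cos)
    }
    total_energy <- total_energy + pmax(energy, 0)
    total_an <- total_an + sum_an
  }
  pc <- total_energy / (total_an + 1e-4 * mean(total_an) + 1e-8)
  pmin(pmax(pc[seq_len(n1), seq_len(n2), drop = FALSE], 0), 1)
}

# Scharr gradient magnitude (the FSIM convention).
scharr_gm <- function(x) {
  fh <- matrix(c(-3, -10, -3, 0, 0, 0, 3, 10, 3), 3, 3) / 16
  gx <- convolve_replicate(x, fh)
  gy <- convolve_replicate(x, t(fh))
  sqrt(gx^2 + gy^2)
}

#' Feature similarity index (FSIM)
#'
#' Full-reference similarity that compares phase-congruency (PC) and
#' gradient-magnitude (GM) maps of the two images, weighting each pixel's
#' agreement by the stronger of the two PC values (the elementwise maximum),
#' so that scores concentrate where either image has salient features.
#' Inputs are jointly rescaled to the 8-bit range before filtering so the
#' stability constants keep their standard meaning.
#'
#' @param x,y Numeric matrices of identical shape.
#' @param cfg An [fsim_config()].
#' @return FSIM score in `[0, 1]`.
#' @export
fsim <- function(x, y, cfg = fsim_config()) {
  assert_image(x, "x"); assert_image(y, "y")
  assert_same_shape(x, y)
  scale <- 255 / max(max(x), max(y), 1e-12)
  fsim_from_features(fsim_features(x * scale, cfg),
                     fsim_features(y * scale, cfg), cfg)
}

# Precomputed per-image FSIM features; lets the sigma sweep reuse the
# fixed image's phase-congruency and gradient maps across the grid.
fsim_features <- function(x8, cfg) {
  list(pc = phase_congruency_map(x8, cfg), gm = scharr_gm(x8))
}

fsim_from_features <- function(f1, f2, cfg) {
  s_pc <- (2 * f1$pc * f2$pc + cfg$t1) / (f1$pc^2 + f2$pc^2 + cfg$t1)
  s_g <- (2 * f1$gm * f2$gm + cfg$t2) / (f1$gm^2 + f2$gm^2 + cfg$t2)
  pcm <- pmax(f1$pc, f2$pc)
  sum(s_pc^cfg$alpha * s_g^cfg$beta * pcm) / (sum(pcm) + 1e-12)
}
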