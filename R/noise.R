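#' Poisson-Gaussian detector noise model
#'
#' The signal-dependent noise of an indirect-conversion detector is modeled
#' as a Poisson-Gaussian mixture: at clean signal level `x` (ADU) the noise
#' standard deviation is `eta(x) = sqrt(alpha * x + beta^2)`, where `alpha`
#' is the Poisson gain (quantum noise, variance per ADU of signal) and `beta`
#' the signal-independent Gaussian read-noise standard deviation in ADU.
#'
#' @param alpha Poisson gain, >= 0.
#' @param beta Gaussian standard deviation in ADU, >= 0.
#' @param mode `"gaussian-approx"` applies `eta(x) * N(0,1)` directly;
#'   `"exact-mixture"` draws scaled Poisson counts plus Gaussian read noise.
#' @return A `noise_model` object.
#' @export
noise_model <- function(alpha, beta, mode = c("gaussian-approx", "exact-mixture")) {
  mode <- match.arg(mode)
  if (!is.numeric(alpha) || alpha < 0) stop_invalid("alpha must be >= 0")
  if (!is.numeric(beta) || beta < 0) stop_invalid("beta must be >= 0")
  structure(list(alpha = alpha, beta = beta, mode = mode),
            class = "noise_model")
}

#' @export
print.noise_model <- function(x, ...) {
  cat(sprintf("Poisson-Gaussian noise model: alpha = %.4g, beta = %.4g ADU (%s)\n",
              x$alpha, x$beta, x$mode))
  invisible(x)
}

#' Apply Poisson-Gaussian noise to a clean image
#'
#' @param clean Nonnegative numeric matrix (ADU).
#' @param model A [noise_model()].
#' @param seed Integer seed; the same seed gives a bit-identical result.
#' @param clip Two-element clipping range in ADU, or `NULL` for none.
#'   Default `c(0, 4095)`, the 12-bit ADC range of the detector profiles.
#' @return Noisy image matrix with the same dimensions.
#' @export
synthesize_noise <- function(clean, model, seed = NULL, clip = c(0, 4095)) {
  assert_image(clean, "clean image", allow_negative = FALSE)
  if (!inherits(model, "noise_model")) stop_invalid("model must be a noise_model")
  if (model$alpha == 0 && model$beta == 0) return(clean)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- length(clean)
  out <- if (model$mode == "gaussian-approx") {
    eta <- sqrt(model$alpha * clean + model$beta^2)
    clean + eta * matrix(stats::rnorm(n), nrow(clean))
  } else {
    shot <- if (model$alpha > 0) {
      model$alpha * matrix(stats::rpois(n, clean / model$alpha), nrow(clean))
    } else {
      clean
    }
    shot + model$beta * matrix(stats::rnorm(n), nrow(clean))
  }
  clip_range(out, clip)
}

#' Estimate the noise-level function from flat-field frames
#'
#' Recovers the Poisson-Gaussian parameters from uniform (flat-field)
#' exposures at several signal levels, following the mean-variance NLF
#' approach: each frame is tiled into blocks, blocks whose pixels show
#' spatial structure are discarded by a Kendall-tau whiteness screen
#' (correlation between pixels and their one-pixel horizontal neighbors),
#' and a robust line is fit to block variance versus block mean. The slope
#' is the Poisson gain `alpha`; the intercept is the Gaussian variance
#' `beta^2` (floored at zero).
#'
#' @param flats List of flat-field matrices spanning >= 3 distinct mean
#'   levels (one or more frames per level).
#' @param block_size Square block side in pixels, >= 8 (default 16).
#' @param uniformity_p Two-sided significance level of the whiteness screen;
#'   blocks whose |tau| exceeds the normal-approximation critical value are
#'   rejected (default 0.01).
#' @return An `nlf_estimate` list: `alpha_hat`, `beta_hat`, a `blocks`
#'   tibble (mean, variance, kept flag) and `n_blocks_kept`.
#' @export
estimate_nlf <- function(flats, block_size = 16, uniformity_p = 0.01) {
  if (is.matrix(flats)) flats <- list(flats)
  if (!is.list(flats) || !length(flats)) stop_invalid("flats must be a list of matrices")
  if (block_size < 8) stop_invalid("block_size must be >= 8")
  means <- vapply(flats, mean, numeric(1))
  if (length(unique(round(means, 3))) < 3)
    stop_invalid("need flats at >= 3 distinct mean levels")

  stats_list <- lapply(flats, function(img) {
    assert_image(img, "flat frame")
    nr <- nrow(img) %/% block_size
    nc <- ncol(img) %/% block_size
    res <- matrix(NA_real_, nr * nc, 3)
    k <- 0L
    for (i in seq_len(nr)) {
      for (j in seq_len(nc)) {
        blk <- img[((i - 1) * block_size + 1):(i * block_size),
                   ((j - 1) * block_size + 1):(j * block_size)]
        k <- k + 1L
        res[k, ] <- c(mean(blk), stats::var(as.vector(blk)),
                      block_whiteness_tau(blk))
      }
    }
    res
  })
  st <- do.call(rbind, stats_list)
  n_pairs <- block_size * (block_size - 1)
  tau_crit <- stats::qnorm(1 - uniformity_p / 2) *
    sqrt(2 * (2 * n_pairs + 5) / (9 * n_pairs * (n_pairs - 1)))
  kept <- abs(st[, 3]) <= tau_crit
  if (sum(kept) < 3)
    stop_invalid("insufficient data: fewer than 3 blocks survive the uniformity screen")

  fit <- MASS::rlm(st[kept, 2] ~ st[kept, 1], maxit = 50)
  slope <- stats::coef(fit)[[2]]
  intercept <- stats::coef(fit)[[1]]
  if (slope < 0) {
    warning("fitted NLF slope negative; alpha_hat floored at 0")
    slope <- 0
  }
  structure(
    list(
      alpha_hat = slope,
      beta_hat = sqrt(max(intercept, 0)),
      blocks = tibble::tibble(mean = st[, 1], variance = st[, 2],
                              tau = st[, 3], kept = kept),
      n_blocks_kept = sum(kept)
    ),
    class = "nlf_estimate"
  )
}

# Kendall tau between block pixels and their one-pixel horizontal neighbors;
# near zero for white noise, large for blocks with spatial structure.
block_whiteness_tau <- function(blk) {
  x <- as.vector(blk[, -ncol(blk)])
  y <- as.vector(blk[, -1])
  stats::cor(x, y, method = "kendall")
}

#' @export
print.nlf_estimate <- function(x, ...) {
  cat(sprintf(
    "NLF estimate: alpha = %.4g, beta = %.4g ADU (%d/%d blocks kept)\n",
    x$alpha_hat, x$beta_hat, x$n_blocks_kept, nrow(x$blocks)))
  invisible(x)
}

#' @export
tidy.nlf_estimate <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha_hat, x$beta_hat)
  )
}
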