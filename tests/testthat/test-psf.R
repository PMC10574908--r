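test_that("gaussian kernel has the documented support, normalization and symmetry", {
  psf <- gaussian_psf_kernel(2.61, truncation_multiple = 4)
  expect_equal(dim(psf$kernel), c(23, 23))
  expect_equal(psf$support_halfwidth, 11L)
  expect_equal(sum(psf$kernel), 1, tolerance = 1e-12)
  expect_true(all(psf$kernel >= 0))

  for (sigma in c(0.4, 1, 3.7)) {
    k <- gaussian_psf_kernel(sigma)$kernel
    center <- (nrow(k) + 1) / 2
    expect_equal(which.max(k), (center - 1) * nrow(k) + center)
    expect_identical(sum(k == max(k)), 1L)
    expect_equal(k, t(k))
    expect_equal(k, k[nrow(k):1, ])            # vertical flip
    expect_equal(k, k[, ncol(k):1])            # horizontal flip
    expect_equal(k, t(k)[nrow(k):1, ])         # 90 degree rotation
  }
})

test_that("kernel marginal reproduces the Gaussian FWHM", {
  # marginal of the separable kernel is the sampled 1D Gaussian; at sigma = 4
  # the sampling is dense enough for an interpolated half-max crossing
  sigma <- 4
  marg <- colSums(gaussian_psf_kernel(sigma)$kernel)
  marg <- marg / max(marg)
  h <- (length(marg) - 1) / 2
  f <- stats::approxfun(seq(-h, h), marg)
  crossing <- stats::uniroot(function(x) f(x) - 0.5, c(0, 3 * sigma))$root
  expect_equal(2 * crossing, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.01)
})

test_that("invalid PSF parameters are rejected", {
  expect_error(gaussian_psf_kernel(0), "positive")
  expect_error(gaussian_psf_kernel(-1), "positive")
  expect_error(gaussian_psf_kernel(1, truncation_multiple = 1), ">= 2")
})

test_that("gaussian MTF model evaluates its closed form", {
  curve <- mtf_from_sigma(1.0, c(0, 0.1, 0.25))
  expect_equal(curve$mtf[1], 1)
  expect_equal(curve$mtf[2], 0.82087, tolerance = 1e-4)
  # monotone in sigma at every positive frequency
  u <- seq(0.05, 0.5, by = 0.05)
  expect_true(all(mtf_from_sigma(1.2, u)$mtf < mtf_from_sigma(0.9, u)$mtf))
  expect_error(mtf_from_sigma(1, c(-0.1, 0.1)), "nonnegative")
  expect_error(mtf_from_sigma(-2), "positive")
})

test_that("sigma round-trips through the MTF fit", {
  for (sigma in c(0.3, 1, 2.61, 5, 8)) {
    curve <- mtf_from_sigma(sigma, seq(0, 0.5, by = 0.005))
    expect_equal(sigma_from_mtf_fit(curve), sigma, tolerance = 1e-6)
  }
  # restricted frequency support still identifies a wide PSF
  curve <- mtf_from_sigma(5.13, seq(0, 0.2, by = 0.004))
  expect_equal(sigma_from_mtf_fit(curve), 5.13, tolerance = 1e-3)
})

test_that("MTF fit tolerates multiplicative measurement noise", {
  sigma <- 2.61
  u <- seq(0.005, 0.25, length.out = 50)
  clean <- mtf_from_sigma(sigma, u)
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    noisy <- clean
    noisy$mtf <- noisy$mtf * (1 + 0.01 * rnorm(50))
    abs(sigma_from_mtf_fit(noisy) - sigma) / sigma
  }, numeric(1))
  expect_lt(median(errs), 0.02)
})

test_that("degenerate MTF curves are rejected", {
  flat <- tibble::tibble(frequency = seq(0, 0.5, 0.05),
                         mtf = rep(0.5, 11))
  expect_error(sigma_from_mtf_fit(flat), "degenerate")
})

test_that("DFT of the kernel marginal matches the continuous MTF", {
  N <- 512
  u <- (0:(N - 1)) / N
  for (sigma in c(1, 2.61, 5.13)) {
    marg <- colSums(gaussian_psf_kernel(sigma)$kernel)
    h <- (length(marg) - 1) / 2
    v <- numeric(N)
    v[(seq(-h, h) %% N) + 1] <- marg
    dft <- Mod(stats::fft(v))
    model <- exp(-2 * pi^2 * sigma^2 * u^2)
    sel <- u <= 0.5 & model > 0.1   # below the aliasing-dominated tail
    expect_lt(max(abs(dft[sel] - model[sel]) / model[sel]), 0.01)
  }
})

test_that("MTF curves round-trip through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  curve <- mtf_from_sigma(1.79, seq(0, 0.4, 0.02))
  write_mtf_csv(curve, path)
  back <- read_mtf_csv(path)
  expect_equal(back$frequency, curve$frequency)
  expect_equal(back$mtf, curve$mtf)
})
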