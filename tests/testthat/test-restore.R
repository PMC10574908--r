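test_that("TV deconvolution with a delta PSF returns the input", {
  fix <- line_fixture(frequencies = c(1, 2.5), group_height = 16,
                      width = 96, margin_rows = 8)
  delta <- matrix(0, 3, 3)
  delta[2, 2] <- 1
  out <- suppressWarnings(deconvolve_tv(fix, delta, tv_config(lambda = 1e-6)))
  expect_lt(rmse(out, fix), 1e-4 * max(fix))
})

test_that("TV deconvolution halves the RMSE of a noiseless blurred chart", {
  fix <- line_fixture()
  psf <- gaussian_psf_kernel(2)
  blurred <- blur_with_sigma(fix, 2)
  out <- suppressWarnings(deconvolve_tv(blurred, psf, tv_config(lambda = 1e-4)))
  expect_lt(rmse(out, fix), 0.5 * rmse(blurred, fix))
})

test_that("the TV objective decreases monotonically", {
  fix <- line_fixture(frequencies = c(1, 2.5), group_height = 16,
                      width = 96, margin_rows = 8)
  deg <- degrade_image(fix, detector_profile("detector2"), seed = 5)
  out <- suppressWarnings(deconvolve_tv(deg, gaussian_psf_kernel(2.61),
                                        tv_config(max_iterations = 50)))
  expect_true(all(diff(attr(out, "objective")) <= 1e-9))
  expect_true(all(out >= 0))
})

test_that("TV solver rejects invalid configurations", {
  fix <- matrix(100, 32, 32)
  bad_kernel <- matrix(1, 3, 3)  # sums to 9
  expect_error(deconvolve_tv(fix, bad_kernel), "normalized")
  expect_error(tv_config(lambda = 0), "positive")
  expect_error(tv_config(tolerance = -1), "positive")
})

test_that("Wiener with K = 0 inverts a periodic blur exactly", {
  set.seed(6)
  x <- matrix(runif(64 * 64, 0, 100), 64, 64)
  k <- gaussian_psf_kernel(1)$kernel
  xb <- adaptpsf:::convolve_periodic(x, k)
  out <- wiener_deconvolve(xb, k, wiener_config(0, taper = FALSE,
                                                boundary = "periodic"))
  expect_lt(rmse(out, x), 1e-6)
})

test_that("Wiener tends to zero as K grows without bound", {
  x <- matrix(runif(32 * 32, 0, 100), 32, 32)
  k <- gaussian_psf_kernel(1)$kernel
  out <- wiener_deconvolve(x, k, wiener_config(1e12))
  expect_lt(max(abs(out)), 1e-6)
  expect_error(wiener_config(-1), ">= 0")
})

test_that("a noisy fixture has an interior optimal Wiener constant", {
  fix <- line_fixture()
  deg <- degrade_image(fix, detector_profile("detector2"), seed = 11)
  Ks <- c(1e-4, 1e-3, 1e-2, 1e-1, 1)
  errs <- vapply(Ks, function(K)
    rmse(wiener_deconvolve(deg, gaussian_psf_kernel(2.61), wiener_config(K)),
         fix), numeric(1))
  best <- which.min(errs)
  expect_gt(best, 1)
  expect_lt(best, length(Ks))
})

test_that("Richardson-Lucy fixes flat images and preserves nonnegativity", {
  flat <- matrix(50, 32, 32)
  k <- gaussian_psf_kernel(1.5)
  expect_equal(richardson_lucy(flat, k, rl_config(7)), flat,
               ignore_attr = TRUE)
  fix <- line_fixture(frequencies = c(1, 2.5), group_height = 16,
                      width = 96, margin_rows = 8)
  deg <- degrade_image(fix, detector_profile("detector2"), seed = 3)
  out <- richardson_lucy(deg, gaussian_psf_kernel(2.61), rl_config(10))
  expect_true(all(out >= 0))
  expect_error(richardson_lucy(matrix(0, 16, 16), k), "all-zero")
})

test_that("Richardson-Lucy conserves flux under periodic boundaries", {
  set.seed(9)
  x <- matrix(runif(48 * 48, 10, 100), 48, 48)
  k <- gaussian_psf_kernel(2)
  out <- richardson_lucy(x, k, rl_config(15, boundary = "periodic"))
  expect_lt(abs(sum(out) - sum(x)) / sum(x), 0.001)
})

test_that("Richardson-Lucy sharpens a blurred point source", {
  pt <- matrix(0, 64, 64)
  pt[32, 32] <- 1
  blurred <- adaptpsf:::convolve_periodic(pt, gaussian_psf_kernel(2)$kernel) *
    1000 + 10
  ratios <- vapply(1:10, function(n) {
    out <- richardson_lucy(blurred, gaussian_psf_kernel(2),
                           rl_config(n, boundary = "periodic"))
    max(out) / sum(out)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("TV restoration sharpens while amplifying less noise than Wiener", {
  fix <- line_fixture()
  deg <- degrade_image(fix, detector_profile("detector2"), seed = 21)
  psf <- gaussian_psf_kernel(2.61)
  tv_out <- suppressWarnings(deconvolve_tv(deg, psf, tv_config()))
  wiener_out <- wiener_deconvolve(deg, psf, wiener_config(1e-4))
  expect_gt(gradient_magnitude(tv_out)$score, gradient_magnitude(deg)$score)
  flat <- flat_roi_rows()
  expect_lt(sd(as.vector(tv_out[flat, ])), sd(as.vector(wiener_out[flat, ])))
})
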