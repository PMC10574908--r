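test_that("SSIM is 1 on identical images, symmetric, and bounded", {
  set.seed(1)
  x <- matrix(runif(64 * 64, 0, 4095), 64, 64)
  y <- blur_with_sigma(x, 1.5)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  expect_lte(ssim(x, y), 1)
  expect_error(ssim(x, y[1:32, ]), "identical dimensions")
})

test_that("SSIM on constant images equals the closed-form luminance term", {
  a <- matrix(100, 32, 32)
  b <- matrix(110, 32, 32)
  C1 <- (0.01 * 4095)^2
  expect_equal(ssim(a, b), (2 * 100 * 110 + C1) / (100^2 + 110^2 + C1))
})

test_that("SSIM and FSIM decrease monotonically with blur of the test image", {
  ref <- line_fixture()
  sigmas <- c(0.5, 1, 2, 4)
  s_scores <- vapply(sigmas, function(s) ssim(ref, blur_with_sigma(ref, s),
                                              ssim_config()), numeric(1))
  f_scores <- vapply(sigmas, function(s) fsim(ref, blur_with_sigma(ref, s)),
                     numeric(1))
  expect_true(all(diff(s_scores) < 0))
  expect_true(all(diff(f_scores) < 0))
})

test_that("CNR matches direct ROI arithmetic and degrades with noise", {
  set.seed(2)
  img <- matrix(rnorm(96 * 96, 500, 10), 96, 96)
  img[20:39, 20:39] <- img[20:39, 20:39] + 200
  rois <- roi_spec(target = c(20, 20, 20, 20), background = c(60, 60, 20, 20))
  tv <- img[20:39, 20:39]
  bv <- img[60:79, 60:79]
  expect_equal(cnr(img, rois),
               (mean(tv) - mean(bv)) / sqrt(var(as.vector(tv)) + var(as.vector(bv))))

  # same pixel distribution in target and background gives zero contrast
  dup <- img
  dup[60:79, 60:79] <- dup[20:39, 20:39]
  expect_equal(cnr(dup, rois), 0)

  # extra noise in both ROIs strictly lowers the score
  noisier <- img + matrix(rnorm(96 * 96, 0, 30), 96, 96)
  expect_lt(cnr(noisier, rois), cnr(img, rois))
})

test_that("multi-ROI CNR averages the per-pair scores", {
  img <- matrix(100, 64, 64)
  img[5:14, 5:14] <- 150
  img[5:14, 30:39] <- 200
  img <- img + matrix(rnorm(64 * 64, 0, 5), 64, 64)
  r1 <- roi_spec(c(5, 5, 10, 10), c(40, 5, 10, 10))
  r2 <- roi_spec(c(5, 30, 10, 10), c(40, 30, 10, 10))
  both <- roi_spec(list(c(5, 5, 10, 10), c(5, 30, 10, 10)),
                   list(c(40, 5, 10, 10), c(40, 30, 10, 10)))
  expect_equal(cnr(img, both), mean(c(cnr(img, r1), cnr(img, r2))))
})

test_that("CNR input contracts are enforced", {
  img <- matrix(100, 32, 32)
  expect_error(cnr(img, roi_spec(c(1, 1, 8, 8), c(4, 4, 8, 8))), "disjoint")
  expect_error(cnr(img, roi_spec(c(1, 1, 8, 8), c(20, 20, 20, 20))), "outside")
  expect_error(cnr(img, roi_spec(c(1, 1, 8, 8), c(20, 20, 8, 8))), "zero variance")
})

test_that("gradient magnitude is zero on constants and exact on a step edge", {
  expect_equal(gradient_magnitude(matrix(7, 32, 32))$score, 0)

  step <- matrix(0, 32, 32)
  step[, 17:32] <- 1
  gm <- gradient_magnitude(step, "sobel")
  # hand-convolved 3x3 Sobel response on a unit vertical step: 4 on the two
  # columns adjacent to the edge, interior rows
  expect_equal(unname(gm$map[10, 16]), 4)
  expect_equal(unname(gm$map[10, 17]), 4)
  expect_equal(unname(gm$map[10, 10]), 0)
  expect_error(gradient_magnitude(step, "canny"), "unknown edge operator")
})

test_that("blurring strictly lowers the mean gradient magnitude", {
  ref <- line_fixture()
  expect_lt(gradient_magnitude(blur_with_sigma(ref, 2))$score,
            gradient_magnitude(ref)$score)
  for (op in c("sobel", "prewitt", "scharr")) {
    expect_lt(gradient_magnitude(blur_with_sigma(ref, 2), op)$score,
              gradient_magnitude(ref, op)$score)
  }
})
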