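test_that("projection of a homogeneous slab matches Beer-Lambert", {
  slab <- structure(list(volume = array(0.02, dim = c(100, 100, 100)),
                         voxel_size_mm = 0.1, mu_material = 0.02),
                    class = "phantom3d")
  geom <- projection_geometry(detector_px = c(32, 32), i0 = 3000)
  proj <- project_phantom(slab, geom)
  expect_equal(proj[16, 16], 3000 * exp(-0.02 * 10), tolerance = 0.005)
  # linearity in source intensity
  geom2 <- projection_geometry(detector_px = c(32, 32), i0 = 6000)
  expect_equal(project_phantom(slab, geom2), 2 * proj)
})

test_that("cone-beam magnification follows similar triangles", {
  ph <- build_dice_phantom(n_voxels = 100, voxel_size_mm = 0.3,
                           mu_material = 0.05)  # 30 mm cube
  geom <- projection_geometry(sdd_mm = 1500, sod_mm = 1000,
                              pixel_pitch_mm = 0.5, detector_px = c(128, 128),
                              i0 = 1000)
  proj <- project_phantom(ph, geom)
  shadow_cols <- range(which(colSums(proj < 0.99 * 1000) > 0))
  width_mm <- diff(shadow_cols) * 0.5
  expect_equal(width_mm, 45, tolerance = 0.04)  # 30 mm at 1.5x
})

test_that("the die phantom carves a small pip volume and vacuum projects flat", {
  ph <- build_dice_phantom(n_voxels = 80)
  frac <- mean(ph$volume == 0)
  expect_gt(frac, 0)
  expect_lt(frac, 0.2)
  expect_error(build_dice_phantom(mu_material = 0), "positive")
  expect_error(build_dice_phantom(n_voxels = 30), ">= 50")

  vac <- structure(list(volume = array(0, c(60, 60, 60)), voxel_size_mm = 0.1,
                        mu_material = 0), class = "phantom3d")
  geom <- projection_geometry(detector_px = c(24, 24), i0 = 3000)
  expect_warning(proj <- project_phantom(vac, geom), "empty projection")
  expect_true(all(proj == 3000))
})

test_that("line chart groups have the requested bar period and modulation", {
  chart <- generate_line_chart()
  groups <- attr(chart, "groups")
  expect_equal(range(groups$frequency), c(0.6, 5.0))
  g2 <- generate_line_chart(frequencies = 2.0)
  expect_equal(attr(g2, "groups")$period_px, 1 / (2.0 * 0.048), tolerance = 1e-9)
  # full modulation within every group of the clean chart
  for (i in seq_len(nrow(groups))) {
    prof <- chart[groups$row_from[i], ]
    expect_equal(max(prof) - min(prof), 2000)
  }
  expect_error(generate_line_chart(frequencies = 12), "Nyquist")
})

test_that("degradation is deterministic and a degenerate profile is identity", {
  fix <- line_fixture(frequencies = c(1, 2.5), group_height = 16,
                      width = 96, margin_rows = 8)
  ident <- make_detector_profile("none", 0, 0, 0)
  expect_identical(degrade_image(fix, ident), fix, ignore_attr = TRUE)
  d1 <- detector_profile("detector1")
  expect_identical(degrade_image(fix, d1, seed = 4),
                   degrade_image(fix, d1, seed = 4))
})

test_that("a thinner scintillator gives a sharper but noisier image", {
  fix <- line_fixture()
  thin <- degrade_image(fix, detector_profile("detector1"), seed = 8)
  thick <- degrade_image(fix, detector_profile("detector3"), seed = 9)
  expect_gt(gradient_magnitude(thin)$score, gradient_magnitude(thick)$score)
  flat <- flat_roi_rows()
  expect_gt(sd(as.vector(thin[flat, ])), sd(as.vector(thick[flat, ])))
})

test_that("a noiseless detector pair recovers the Table-style width difference", {
  ph <- build_dice_phantom(n_voxels = 100, voxel_size_mm = 0.15,
                           mu_material = 0.1)
  geom <- projection_geometry(pixel_pitch_mm = 0.12, detector_px = c(96, 96),
                              i0 = 3000)
  proj <- project_phantom(ph, geom)
  thin <- degrade_image(proj, make_detector_profile("thin0", 1.79, 0, 0))
  thick <- degrade_image(proj, make_detector_profile("thick0", 2.61, 0, 0))
  step <- 0.1
  sw <- sweep_sigma(thin, thick, sigma_grid(1.2, 2.6, step))
  expect_lte(abs(as.numeric(sw$sigma_final) - sqrt(2.61^2 - 1.79^2)),
             2 * step + 1e-9)
})

test_that("simulator outputs are bit-identical under a fixed seed", {
  fix <- line_fixture(frequencies = c(1, 2.5), group_height = 16,
                      width = 96, margin_rows = 8)
  p <- detector_profile("detector2")
  expect_identical(degrade_image(fix, p, seed = 123),
                   degrade_image(fix, p, seed = 123))
  m <- noise_model(0.29, 7.10, "exact-mixture")
  expect_identical(synthesize_noise(fix, m, seed = 7),
                   synthesize_noise(fix, m, seed = 7))
})
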