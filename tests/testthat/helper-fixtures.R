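# Fixtures built in code: line-pattern charts, slit images, small blur helpers.

rmse <- function(a, b) sqrt(mean((a - b)^2))

blur_with_sigma <- function(img, sigma) {
  adaptpsf:::convolve_replicate(img, gaussian_psf_kernel(sigma)$kernel)
}

# Standard line-pattern fixture: a few bar groups plus a blank margin block
# usable as a flat ROI for noise measurements.
line_fixture <- function(frequencies = c(0.8, 1.5, 2.5, 4),
                         group_height = 20, width = 160, margin_rows = 24) {
  chart <- generate_line_chart(frequencies = frequencies,
                               group_height = group_height, width = width)
  rbind(matrix(1000, margin_rows, width), chart)
}

flat_roi_rows <- function(margin_rows = 24) seq_len(margin_rows - 4)

# Synthetic tilted slit: Gaussian profile of perpendicular distance to a
# line through the image center at the given tilt.
slit_image <- function(nr = 200, nc = 64, tilt_deg = 2, sigma = 2,
                       amp = 1000, base = 100) {
  b <- tan(tilt_deg * pi / 180)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- (cols - (nc / 2 + b * (rows - nr / 2))) / sqrt(1 + b^2)
  base + amp * exp(-d^2 / (2 * sigma^2))
}

# Flat-field stacks for NLF tests.
make_flats <- function(alpha, beta, seed, n = 256,
                       levels = c(200, 500, 1000, 2000, 3000)) {
  m <- noise_model(alpha, beta)
  lapply(seq_along(levels), function(i)
    synthesize_noise(matrix(levels[i], n, n), m, seed = seed * 100 + i))
}
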