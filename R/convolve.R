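# Convolution backends. Spatial (replicate-padded) convolution is delegated to
# EBImage::filter2; periodic convolution is done through the OTF so the
# frequency-domain restoration solvers and their tests share one code path.

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Convolve with replicate (edge-clamp) padding; avoids wrap-around bias at
# image borders during the sigma sweep.
convolve_replicate <- function(img, kernel) {
  EBImage::filter2(img, kernel, boundary = "replicate")
}

# Embed a centered, odd-sized PSF kernel into an optical transfer function of
# the given image dimensions (kernel center moved to element [1,1]).
psf_to_otf <- function(kernel, dim_out) {
  kh <- nrow(kernel)
  kw <- ncol(kernel)
  if (kh > dim_out[1] || kw > dim_out[2])
    stop_invalid("kernel larger than image")
  pad <- matrix(0, dim_out[1], dim_out[2])
  pad[seq_len(kh), seq_len(kw)] <- kernel
  # circular shift so the kernel center lands on [1,1]
  shift_r <- -((kh - 1L) %/% 2L)
  shift_c <- -((kw - 1L) %/% 2L)
  idx_r <- ((seq_len(dim_out[1]) - 1L - shift_r) %% dim_out[1]) + 1L
  idx_c <- ((seq_len(dim_out[2]) - 1L - shift_c) %% dim_out[2]) + 1L
  fft2(pad[idx_r, idx_c])
}

convolve_periodic <- function(img, kernel) {
  H <- psf_to_otf(kernel, dim(img))
  Re(ifft2(fft2(img) * H))
}

# Replicate-pad an image by p pixels on every side (edge clamp); the
# frequency-domain solvers pad, solve periodically, and crop back so the
# wrap-around seam lies outside the restored field of view.
pad_replicate <- function(img, p) {
  img <- img[c(rep(1L, p), seq_len(nrow(img)), rep(nrow(img), p)), , drop = FALSE]
  img[, c(rep(1L, p), seq_len(ncol(img)), rep(ncol(img), p)), drop = FALSE]
}

crop_pad <- function(img, p, dim_orig) {
  img[(p + 1):(p + dim_orig[1]), (p + 1):(p + dim_orig[2]), drop = FALSE]
}

# Blend the image border toward its blurred self so periodic frequency-domain
# solvers do not ring at the frame edge (raised-cosine ramp of the kernel
# half-width, in the spirit of the classic edge-taper preconditioning).
edge_taper <- function(img, kernel) {
  w <- max((nrow(kernel) - 1L) %/% 2L, 1L)
  ramp <- function(n) {
    r <- rep(1, n)
    m <- min(w, n %/% 2)
    if (m > 0) {
      t <- 0.5 * (1 - cos(pi * seq_len(m) / (m + 1)))
      r[seq_len(m)] <- t
      r[n + 1 - seq_len(m)] <- t
    }
    r
  }
  wmat <- outer(ramp(nrow(img)), ramp(ncol(img)))
  blurred <- convolve_replicate(img, kernel)
  img * wmat + blurred * (1 - wmat)
}
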