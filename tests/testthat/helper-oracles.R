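# Shared oracles and small fixtures, built in code.

# Exact subpixel circular shift via the Fourier shift theorem.
fourier_shift <- function(img, dy, dx) {
  fy <- chromashift:::fft_freq(nrow(img))
  fx <- chromashift:::fft_freq(ncol(img))
  ph <- outer(exp(-2i * pi * fy * dy), exp(-2i * pi * fx * dx))
  Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / length(img)
}

fourier_shift_3d <- function(vol, dz, dy, dx) {
  d <- dim(vol)
  fz <- chromashift:::fft_freq(d[1])
  fy <- chromashift:::fft_freq(d[2])
  fx <- chromashift:::fft_freq(d[3])
  ph <- outer(outer(exp(-2i * pi * fz * dz), exp(-2i * pi * fy * dy)),
              exp(-2i * pi * fx * dx))
  dim(ph) <- d
  Re(stats::fft(stats::fft(vol) * ph, inverse = TRUE)) / length(vol)
}

# A smooth band-limited random test image (reproducible).
smooth_image <- function(n = 128, seed = 1, sigma_f = 0.04) {
  set.seed(seed)
  base <- matrix(stats::rnorm(n * n), n, n)
  f <- chromashift:::fft_freq(n)
  g <- outer(exp(-f^2 / (2 * sigma_f^2)), exp(-f^2 / (2 * sigma_f^2)))
  img <- Re(stats::fft(stats::fft(base) * g, inverse = TRUE)) / (n * n)
  img <- img - min(img)
  img / max(img)
}

quiet_global <- function(...) suppressWarnings(estimate_global(...))
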