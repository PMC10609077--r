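# Small Fourier helpers shared by the simulator, the aligner and the metrics.
# Images are matrices indexed [x, y] (x is the MRC fast axis); frequencies are
# in cycles per pixel.

#' Discrete Fourier frequencies
#'
#' Frequencies of the length-`n` DFT in cycles per sample, in FFT order
#' (DC first, negative frequencies wrapped to the tail).
#'
#' @param n number of samples.
#' @return numeric vector of length `n` in `(-0.5, 0.5]`.
#' @keywords internal
fft_freqs <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# Matrices of per-pixel frequency components, FFT order.
freq_grid <- function(nx, ny) {
  list(
    fx = matrix(fft_freqs(nx), nx, ny),
    fy = matrix(fft_freqs(ny), nx, ny, byrow = TRUE)
  )
}

ifft2 <- function(X) stats::fft(X, inverse = TRUE) / length(X)

#' Low-pass transfer function
#'
#' Amplitude transfer function on the FFT grid. The raised-cosine filter is
#' flat up to `(1 - transition) * cutoff`, tapers with a half-cosine and
#' reaches zero exactly at `cutoff`, so no energy survives beyond the cutoff.
#' The Gaussian filter has its half-maximum at `cutoff` and a long tail.
#'
#' @param nx,ny image dimensions in pixels.
#' @param cutoff cutoff frequency, cycles/pixel.
#' @param type `"raised-cosine"` (default) or `"gaussian"`.
#' @param transition fractional width of the raised-cosine taper.
#' @return an `nx` by `ny` matrix of amplitudes in `[0, 1]`.
#' @keywords internal
lowpass_transfer <- function(nx, ny, cutoff,
                             type = c("raised-cosine", "gaussian"),
                             transition = 0.25) {
  type <- match.arg(type)
  g <- freq_grid(nx, ny)
  f <- sqrt(g$fx^2 + g$fy^2)
  if (type == "gaussian") {
    return(exp(-log(2) * (f / cutoff)^2))
  }
  f1 <- cutoff * (1 - transition)
  H <- matrix(0, nx, ny)
  H[f <= f1] <- 1
  band <- f > f1 & f < cutoff
  H[band] <- 0.5 * (1 + cos(pi * (f[band] - f1) / (cutoff - f1)))
  H
}

# Apply an amplitude transfer function to a real image; returns a real image.
fft_filter <- function(img, H) {
  Re(ifft2(stats::fft(img) * H))
}

# Gaussian blur with real-space standard deviation sigma (pixels), done in
# the frequency domain (periodic boundary).
fft_gaussian_blur <- function(img, sigma) {
  g <- freq_grid(nrow(img), ncol(img))
  H <- exp(-2 * pi^2 * sigma^2 * (g$fx^2 + g$fy^2))
  fft_filter(img, H)
}

#' Sub-pixel translation by Fourier phase ramp
#'
#' Returns the periodically wrapped image `out(p) = img(p + c(dx, dy))`,
#' i.e. it samples the input `dx`/`dy` pixels ahead along x/y.
#'
#' @param img numeric matrix.
#' @param dx,dy sampling offsets in pixels (may be fractional).
#' @return numeric matrix of the same dimensions.
#' @keywords internal
translate_fourier <- function(img, dx, dy) {
  g <- freq_grid(nrow(img), ncol(img))
  ramp <- exp(2i * pi * (g$fx * dx + g$fy * dy))
  Re(ifft2(stats::fft(img) * ramp))
}
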