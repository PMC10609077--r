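# Per-micrograph quality measures: window triplets, trimmed coefficient of
# variation, radially averaged power spectral density, the PSD-drop
# resolution limit, and shift-recovery error against the ground truth.

#' Extract the evaluation window triplet
#'
#' Three crops of `window` pixels square: top-left corner, centre, and
#' bottom-right corner of the micrograph, plus a normalized (mean 0, sd 1)
#' copy of the centre window.
#'
#' @param micrograph numeric matrix, at least `window` pixels in each
#'   dimension.
#' @param window crop size in pixels (default 512).
#' @return list with matrices `top_left`, `center`, `bottom_right`,
#'   `center_normalized`, and `offsets` (0-based crop origins).
#' @export
extract_windows <- function(micrograph, window = 512) {
  nx <- nrow(micrograph); ny <- ncol(micrograph)
  if (nx < window || ny < window) {
    stop(sprintf("micrograph smaller than the %d px window", window))
  }
  off <- rbind(top_left = c(0, 0),
               center = c((nx - window) %/% 2, (ny - window) %/% 2),
               bottom_right = c(nx - window, ny - window))
  crop <- function(o) micrograph[(o[1] + 1):(o[1] + window),
                                 (o[2] + 1):(o[2] + window)]
  ctr <- crop(off["center", ])
  s <- sd(ctr)
  if (s == 0) stop("degenerate centre window: zero standard deviation")
  list(top_left = crop(off["top_left", ]),
       center = ctr,
       bottom_right = crop(off["bottom_right", ]),
       center_normalized = (ctr - mean(ctr)) / s,
       offsets = off)
}

#' Histogram and trimmed coefficient of variation
#'
#' Histogram of the raw (un-normalized) micrograph values, and the
#' coefficient of variation computed after removing outliers by the
#' interquantile-range method: with `iqr_fraction = 0.80` the inner range is
#' `IQR80 = Q90 - Q10` and values outside
#' `[Q10 - fence * IQR80, Q90 + fence * IQR80]` are discarded before
#' `CV = 100 * sd / mean`.
#'
#' @param micrograph numeric matrix or vector.
#' @param iqr_fraction central probability mass defining the quantile pair.
#' @param fence multiple of the interquantile range for the outlier fence.
#' @param breaks passed to [graphics::hist()] (computed without plotting).
#' @return list with `cv` (percent), `histogram`, `n_trimmed`, `quantiles`.
#' @export
histogram_cv <- function(micrograph, iqr_fraction = 0.80, fence = 1.5,
                         breaks = 100) {
  v <- as.vector(micrograph)
  if (length(v) == 0) stop("empty input")
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  p_lo <- (1 - iqr_fraction) / 2
  q <- quantile(v, c(p_lo, 1 - p_lo), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- v >= q[1] - fence * iqr & v <= q[2] + fence * iqr
  vt <- v[keep]
  m <- mean(vt)
  if (!is.finite(m) || abs(m) < .Machine$double.eps * max(1, max(abs(vt)))) {
    stop("undefined CV: trimmed mean is zero")
  }
  list(cv = 100 * sd(vt) / m, histogram = h,
       n_trimmed = sum(!keep), quantiles = q)
}

#' Radially averaged power spectral density
#'
#' Azimuthally averages the squared FFT magnitude into radial bins. The
#' per-pixel frequency magnitude is computed in cycles/pixel (per-axis
#' normalized frequencies, so rectangular images are handled), and binned by
#' integer-rounded radius at the resolution of the smaller image dimension;
#' the reported profile spans DC to Nyquist.
#'
#' @param micrograph numeric matrix with both dimensions >= 64.
#' @param pixel_size Angstrom per pixel.
#' @return an object of class `radial_psd`: a data.frame with columns
#'   `freq` (cycles/pixel), `resolution_A`, `power` (mean power per bin) and
#'   `log10_power`, carrying attributes `pixel_size`, `energy` (sum of
#'   squared image values) and `total_power_by_bin` (full-plane bin sums of
#'   `|FFT|^2 / N`, whose total equals the image energy by Parseval).
#' @export
radial_psd <- function(micrograph, pixel_size = 1) {
  nx <- nrow(micrograph); ny <- ncol(micrograph)
  if (min(nx, ny) < 64) stop("image must be at least 64 px in each dimension")
  P <- Mod(stats::fft(micrograph))^2
  g <- freq_grid(nx, ny)
  f <- sqrt(g$fx^2 + g$fy^2)
  m <- min(nx, ny)
  bin <- as.integer(round(f * m))
  mean_by_bin <- tapply(as.vector(P), bin, mean)
  total_by_bin <- tapply(as.vector(P), bin, sum) / (nx * ny)
  nyq_bin <- m %/% 2
  bins <- 0:nyq_bin
  pw <- as.numeric(mean_by_bin[as.character(bins)])
  freq <- bins / m
  df <- data.frame(freq = freq,
                   resolution_A = ifelse(freq > 0, pixel_size / freq, Inf),
                   power = pw,
                   log10_power = log10(pmax(pw, .Machine$double.xmin)))
  attr(df, "pixel_size") <- pixel_size
  attr(df, "energy") <- sum(micrograph^2)
  attr(df, "total_power_by_bin") <- total_by_bin
  class(df) <- c("radial_psd", "data.frame")
  df
}

#' PSD-drop resolution limit
#'
#' The resolution (Angstrom) of the first frequency bin whose radial PSD
#' falls below `1/threshold` of the PSD at the origin; if the profile never
#' drops below the threshold the Nyquist resolution `2 * pixel_size` is
#' returned. With `reference = "first"` the first non-DC bin replaces true
#' DC as the reference (useful when an apodization taper redistributes the
#' DC power).
#'
#' @param psd a `radial_psd` (or a data.frame with `freq` and `power`).
#' @param pixel_size Angstrom per pixel; defaults to the value carried by
#'   `psd`.
#' @param threshold drop factor (default 100).
#' @param reference `"dc"` (default) or `"first"`.
#' @return resolution limit in Angstrom.
#' @export
psd_resolution_limit <- function(psd, pixel_size = NULL, threshold = 100,
                                 reference = c("dc", "first")) {
  reference <- match.arg(reference)
  if (is.null(pixel_size)) pixel_size <- attr(psd, "pixel_size")
  if (is.null(pixel_size)) pixel_size <- 1
  stopifnot(is.data.frame(psd), all(c("freq", "power") %in% names(psd)))
  ord <- order(psd$freq)
  freq <- psd$freq[ord]
  pw <- psd$power[ord]
  if (freq[1] != 0) stop("psd must contain a DC bin")
  ref_power <- if (reference == "dc") pw[1] else pw[2]
  below <- which(freq > 0 & pw < ref_power / threshold)
  if (length(below) == 0) return(2 * pixel_size)
  pixel_size / freq[min(below)]
}

#' Shift-recovery error
#'
#' Root-mean-square Euclidean error between the estimated and true
#' per-frame shifts, after re-referencing both trajectories to the
#' estimator's reference frame (so any common offset is gauge, not error).
#'
#' @param estimated a `global_alignment` (or an n x 2 shift matrix).
#' @param truth a [motion_ground_truth()] (or an n x 2 shift matrix).
#' @param reference_frame reference frame index; defaults to the
#'   estimator's.
#' @return RMSE in pixels.
#' @export
shift_rmse <- function(estimated, truth, reference_frame = NULL) {
  est <- if (inherits(estimated, "global_alignment")) estimated$shifts else estimated
  tru <- if (inherits(truth, "motion_ground_truth")) truth$shifts else truth
  if (nrow(est) != nrow(tru)) stop("frame-count mismatch between estimate and truth")
  ref <- if (!is.null(reference_frame)) reference_frame
         else if (inherits(estimated, "global_alignment")) estimated$reference_frame
         else 1L
  est <- sweep(est, 2, est[ref, ])
  tru <- sweep(tru, 2, tru[ref, ])
  sqrt(mean(rowSums((est - tru)^2)))
}
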