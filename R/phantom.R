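# Phantom movie synthesis: deterministic frames built from a static content
# image (simulated ice plus a grid/disc/cross signal) deformed per frame by
# the ground-truth motion, with optional Poisson electron-counting noise.

#' Ice simulation parameters
#'
#' The amorphous ice background is modelled as an i.i.d. Gaussian random
#' field that is low-pass filtered (default cutoff 3 Angstrom, i.e. no
#' structure finer than the filter resolution survives) and then linearly
#' rescaled to a fixed intensity range (default `[0, 2]` mean electrons).
#'
#' @param mean,sd parameters of the generating normal distribution.
#' @param lowpass_resolution filter cutoff in Angstrom (>= 2 * pixel size).
#' @param rescale_min,rescale_max output range after rescaling.
#' @param filter filter shape: `"raised-cosine"` (zero beyond the cutoff,
#'   default) or `"gaussian"` (half-maximum at the cutoff).
#' @return an object of class `ice_spec`.
#' @export
ice_spec <- function(mean = 0, sd = 1, lowpass_resolution = 3,
                     rescale_min = 0, rescale_max = 2,
                     filter = c("raised-cosine", "gaussian")) {
  if (sd <= 0) stop("ice sd must be > 0")
  if (rescale_min >= rescale_max) stop("rescale_min must be < rescale_max")
  structure(list(mean = mean, sd = sd,
                 lowpass_resolution = lowpass_resolution,
                 rescale_min = rescale_min, rescale_max = rescale_max,
                 filter = match.arg(filter)),
            class = "ice_spec")
}

#' Full recipe for one phantom movie
#'
#' @param dims frame dimensions `c(nx, ny)` in pixels (>= 16).
#' @param n_frames number of frames (>= 1).
#' @param pixel_size sampling rate, Angstrom per pixel.
#' @param signal signal pattern: `"grid"`, `"disc"` or `"cross"`.
#' @param grid_step grid spacing / disc lattice spacing, pixels.
#' @param line_width grid/cross line width, pixels (`0 < line_width < grid_step`).
#' @param signal_amplitude mean electrons added where the signal is present.
#' @param disc_radius disc radius, pixels.
#' @param disc_layout `"lattice"` (discs on a `grid_step` lattice) or
#'   `"center"` (one disc at the frame centre).
#' @param cross_arm half arm length of the cross, pixels (default a third of
#'   the smaller frame dimension).
#' @param ice an [ice_spec()], or `NULL` for no ice.
#' @param dose if `TRUE`, sample Poisson electron counts from the
#'   deterministic frames.
#' @param seed integer seed making ice and dose reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims, n_frames, pixel_size = 1,
                         signal = c("grid", "disc", "cross"),
                         grid_step = 150, line_width = 5,
                         signal_amplitude = 1,
                         disc_radius = 20,
                         disc_layout = c("lattice", "center"),
                         cross_arm = NULL,
                         ice = NULL, dose = FALSE, seed = 1L) {
  signal <- match.arg(signal)
  stopifnot(length(dims) == 2, n_frames >= 1, pixel_size > 0)
  if (any(dims < 16)) stop("dims must be >= 16 pixels")
  if (line_width <= 0) stop("line_width must be > 0")
  if (grid_step <= line_width) stop("grid_step must exceed line_width")
  if (!is.null(ice)) {
    stopifnot(inherits(ice, "ice_spec"))
    if (ice$lowpass_resolution < 2 * pixel_size) {
      stop("ice lowpass_resolution below Nyquist (2 * pixel_size)")
    }
  }
  structure(list(dims = as.integer(dims), n_frames = as.integer(n_frames),
                 pixel_size = pixel_size, signal = signal,
                 grid_step = grid_step, line_width = line_width,
                 signal_amplitude = signal_amplitude,
                 disc_radius = disc_radius,
                 disc_layout = match.arg(disc_layout),
                 cross_arm = if (is.null(cross_arm)) min(dims) %/% 3 else cross_arm,
                 ice = ice, dose = isTRUE(dose), seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Movie frame stack
#'
#' Thin container for an ordered stack of frames: a 3-D array indexed
#' `[x, y, frame]` plus the pixel size. Values are mean electron counts per
#' pixel, or integer counts after dose sampling (`counts = TRUE`).
#'
#' @param data 3-D numeric array `[nx, ny, n_frames]` (a matrix is treated
#'   as a single frame).
#' @param pixel_size Angstrom per pixel.
#' @param counts whether values are sampled integer counts.
#' @return an object of class `frame_stack`.
#' @export
frame_stack <- function(data, pixel_size = 1, counts = FALSE) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3, pixel_size > 0)
  structure(list(data = data, pixel_size = pixel_size, counts = counts),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("frame_stack: %d x %d px, %d frame(s), %.3g A/px, %s\n",
              d[1], d[2], d[3], x$pixel_size,
              if (x$counts) "integer counts" else "mean electron counts"))
  invisible(x)
}

#' Render the noise-free signal pattern
#'
#' Grid: horizontal plus vertical lines of `line_width` pixels at period
#' `grid_step`, with lines anchored at 0-based columns/rows that are
#' multiples of the step (each line spans `[c, c + line_width)`). Disc: discs
#' of radius `disc_radius` either centred or on a lattice. Cross: one centred
#' plus-shaped pattern. The signal takes the value `signal_amplitude` on the
#' pattern and 0 elsewhere.
#'
#' @param spec a [phantom_spec()].
#' @return numeric matrix `dims[1]` by `dims[2]`.
#' @export
render_signal <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nx <- spec$dims[1]; ny <- spec$dims[2]
  xin <- ((seq_len(nx) - 1) %% spec$grid_step) < spec$line_width
  yin <- ((seq_len(ny) - 1) %% spec$grid_step) < spec$line_width
  mask <- switch(spec$signal,
    grid = outer(xin, rep(TRUE, ny)) | outer(rep(TRUE, nx), yin),
    disc = {
      centers <- if (spec$disc_layout == "center") {
        matrix(c((nx + 1) / 2, (ny + 1) / 2), 1, 2)
      } else {
        cxs <- seq(spec$grid_step / 2, nx, by = spec$grid_step)
        cys <- seq(spec$grid_step / 2, ny, by = spec$grid_step)
        as.matrix(expand.grid(cxs, cys))
      }
      m <- matrix(FALSE, nx, ny)
      X <- matrix(seq_len(nx), nx, ny)
      Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
      for (i in seq_len(nrow(centers))) {
        m <- m | ((X - centers[i, 1])^2 + (Y - centers[i, 2])^2 <=
                    spec$disc_radius^2)
      }
      m
    },
    cross = {
      cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
      X <- matrix(seq_len(nx), nx, ny)
      Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
      hw <- spec$line_width / 2
      (abs(X - cx) < hw & abs(Y - cy) <= spec$cross_arm) |
        (abs(Y - cy) < hw & abs(X - cx) <= spec$cross_arm)
    })
  mask * spec$signal_amplitude
}

#' Simulate the ice background
#'
#' Draws an i.i.d. field from `Normal(mean, sd^2)`, low-pass filters it at
#' the spatial frequency `pixel_size / lowpass_resolution` cycles/pixel, and
#' linearly rescales so that the observed minimum and maximum map exactly to
#' `rescale_min` and `rescale_max`. Deterministic given `seed`.
#'
#' @param dims `c(nx, ny)` in pixels.
#' @param ice an [ice_spec()].
#' @param pixel_size Angstrom per pixel.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return numeric matrix with range exactly `[rescale_min, rescale_max]`.
#' @export
simulate_ice <- function(dims, ice = ice_spec(), pixel_size = 1, seed = NULL) {
  stopifnot(inherits(ice, "ice_spec"), length(dims) == 2, all(dims >= 2))
  if (ice$lowpass_resolution < 2 * pixel_size) {
    stop("lowpass_resolution below Nyquist (2 * pixel_size)")
  }
  if (!is.null(seed)) set.seed(seed)
  field <- matrix(rnorm(prod(dims), ice$mean, ice$sd), dims[1], dims[2])
  cutoff <- pixel_size / ice$lowpass_resolution
  H <- lowpass_transfer(dims[1], dims[2], cutoff, type = ice$filter)
  field <- fft_filter(field, H)
  rng <- range(field)
  if (rng[1] == rng[2]) stop("degenerate ice field (constant after filtering)")
  (field - rng[1]) / (rng[2] - rng[1]) *
    (ice$rescale_max - ice$rescale_min) + ice$rescale_min
}

#' Render the deterministic frames of a phantom movie
#'
#' Builds one static content image (ice, if enabled, plus the signal) and
#' warps it by [displacement_field()] for every frame, so the ice structure
#' is simulated once and deformed along the movie. Warping uses bicubic
#' interpolation; samples falling outside the content are filled with the
#' content mean to avoid spurious edges. Frames with zero shift and zero
#' doming take a fast identity path and are bit-identical to the content.
#'
#' @param spec a [phantom_spec()] (its `dose` flag is ignored here).
#' @param truth a [motion_ground_truth()] with matching frame count/dims.
#' @param content optional precomputed content image (e.g. to reuse an ice
#'   field); defaults to ice (if any) plus signal.
#' @return a [frame_stack()] of mean electron counts.
#' @export
render_movie <- function(spec, truth, content = NULL) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(truth, "motion_ground_truth"))
  if (truth$n_frames != spec$n_frames) stop("truth frame count mismatch")
  if (!all(truth$dims == spec$dims)) stop("truth dims mismatch")
  if (is.null(content)) {
    content <- render_signal(spec)
    if (!is.null(spec$ice)) {
      content <- content +
        simulate_ice(spec$dims, spec$ice, spec$pixel_size, seed = spec$seed)
    }
  }
  nx <- spec$dims[1]; ny <- spec$dims[2]
  fill <- mean(content)
  frames <- array(0, c(nx, ny, spec$n_frames))
  for (t in 0:(spec$n_frames - 1)) {
    s <- truth$shifts[t + 1, ]
    k <- truth$k[t + 1, ]
    if (all(s == 0) && all(k == 0)) {
      frames[, , t + 1] <- content
    } else {
      m <- displacement_field(truth, t)
      frames[, , t + 1] <- warp_image(content, m$sx, m$sy,
                                      method = "bicubic", fill = fill)
    }
  }
  frame_stack(frames, pixel_size = spec$pixel_size)
}

#' Sample Poisson electron counts
#'
#' Treats the deterministic frame values as per-pixel Poisson means and
#' replaces each pixel by an independent draw. Negative means (possible
#' after interpolation overshoot) are clipped to zero; the number of clipped
#' pixels is recorded in the `clipped` attribute and reported via a message.
#'
#' @param frames a [frame_stack()] of mean electron counts.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return a [frame_stack()] of integer counts (`counts = TRUE`) with
#'   attribute `clipped`.
#' @export
apply_dose <- function(frames, seed = NULL) {
  stopifnot(inherits(frames, "frame_stack"))
  if (!is.null(seed)) set.seed(seed)
  lam <- frames$data
  n_neg <- sum(lam < 0)
  if (n_neg > 0) {
    message(sprintf("apply_dose: clipped %d negative mean(s) to 0", n_neg))
    lam[lam < 0] <- 0
  }
  counts <- array(rpois(length(lam), as.vector(lam)), dim(lam))
  out <- frame_stack(counts, pixel_size = frames$pixel_size, counts = TRUE)
  attr(out, "clipped") <- n_neg
  out
}

#' Gain and dark reference images
#'
#' Flat references at movie dimensions: gain all ones, dark all zeros, so
#' that applying the correction `(raw - dark) * gain` is a no-op. Useful for
#' exercising the correction path of alignment programs.
#'
#' @param dims `c(nx, ny)` in pixels.
#' @return list with matrices `gain` and `dark`.
#' @export
generate_gain_dark <- function(dims) {
  stopifnot(length(dims) == 2, all(dims >= 1))
  list(gain = matrix(1, dims[1], dims[2]),
       dark = matrix(0, dims[1], dims[2]))
}

#' Simulate a complete phantom movie
#'
#' End-to-end generation: ground-truth motion, deterministic frames, and
#' (optionally) Poisson dose sampling. The ice is seeded with `spec$seed`
#' and the dose with `spec$seed + 1`, so identical specs give bit-identical
#' movies.
#'
#' @param spec a [phantom_spec()].
#' @param shift a [shift_model()], [fixed_step_model()], or `NULL`.
#' @param doming a [deformation_schedule()] (its `n_frames` must match), or
#'   `NULL`.
#' @return list with elements `frames` (a [frame_stack()]) and `truth`
#'   (a [motion_ground_truth()]).
#' @export
simulate_movie <- function(spec, shift = NULL, doming = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- motion_ground_truth(spec$n_frames, spec$dims,
                               shift = shift, doming = doming)
  frames <- render_movie(spec, truth)
  if (spec$dose) frames <- apply_dose(frames, seed = spec$seed + 1L)
  list(frames = frames, truth = truth)
}

#' Generate a sweep of fixed-step shift movies
#'
#' One movie per total drift in `seq(from, to, by)` (the 50:120:10 sweep of
#' the default arguments yields eight movies), written as MRC stacks with
#' JSON ground-truth sidecars.
#'
#' @param spec a [phantom_spec()] shared by all movies.
#' @param from,to,by total-shift sweep in pixels.
#' @param direction drift direction (see [fixed_step_model()]).
#' @param doming optional [deformation_schedule()] applied to every movie.
#' @param out_dir output directory (created if missing).
#' @return invisibly, a data.frame with columns `total_shift`, `movie`,
#'   `ground_truth` (file paths).
#' @export
simulate_shift_sweep <- function(spec, from = 50, to = 120, by = 10,
                                 direction = c(1, 1), doming = NULL,
                                 out_dir = ".") {
  totals <- seq(from, to, by = by)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- lapply(totals, function(tot) {
    mv <- simulate_movie(spec,
                         shift = fixed_step_model(tot, spec$n_frames, direction),
                         doming = doming)
    movie_path <- file.path(out_dir, sprintf("phantom_shift%03d.mrc", tot))
    gt_path <- file.path(out_dir, sprintf("phantom_shift%03d_gt.json", tot))
    write_mrc(mv$frames, movie_path)
    write_ground_truth(mv$truth, gt_path)
    data.frame(total_shift = tot, movie = movie_path,
               ground_truth = gt_path, stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, rows))
}
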