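# Ground-truth motion for phantom movies: per-frame global drift (parametric
# or fixed-step), a per-frame schedule of radial doming coefficients, and the
# composed per-pixel displacement field used to render each frame.

#' Parametric drift model
#'
#' Global per-frame drift of the form
#' \deqn{x(t) = a_1 t + a_2 t^2 + \cos(t)/10, \quad
#'       y(t) = b_1 t + b_2 t^2 + \sin(t^2)/5}
#' with trigonometric arguments in radians. The linear terms capture stage
#' drift, the quadratic terms curvature of the trajectory, and the bounded
#' trigonometric terms small oscillations. The defaults emulate drift
#' magnitudes commonly seen in cryo-EM exposures.
#'
#' @param a1,a2 x-direction linear and quadratic coefficients.
#' @param b1,b2 y-direction linear and quadratic coefficients.
#' @return an object of class `shift_model`.
#' @export
#' @examples
#' eval_shift(shift_model(), t = 0)  # c(0.1, 0)
shift_model <- function(a1 = -0.039, a2 = 0.002, b1 = -0.02, b2 = 0.002) {
  co <- c(a1 = a1, a2 = a2, b1 = b1, b2 = b2)
  if (!all(is.finite(co))) stop("shift_model coefficients must be finite")
  structure(as.list(co), class = "shift_model")
}

#' Evaluate the parametric drift at a frame index
#'
#' @param model a [shift_model()].
#' @param t frame index (>= 0); may be a vector.
#' @return for scalar `t`, a named length-2 vector `c(x, y)` in pixels; for
#'   vector `t`, a matrix with one row per index and columns `x`, `y`.
#' @export
eval_shift <- function(model, t) {
  stopifnot(inherits(model, "shift_model"), all(t >= 0))
  x <- model$a1 * t + model$a2 * t^2 + cos(t) / 10
  y <- model$b1 * t + model$b2 * t^2 + sin(t^2) / 5
  if (length(t) == 1L) c(x = x, y = y) else cbind(x = x, y = y)
}

#' Fixed-step drift model
#'
#' Uniform drift along a fixed direction: frame 0 sits at zero shift and the
#' final frame at `total_shift` pixels from it, with equal steps in between.
#' Used for the controlled shift sweeps (total drifts of 50-120 pixels).
#'
#' @param total_shift total drift over the movie, pixels (>= 0).
#' @param n_frames number of frames (>= 2).
#' @param direction length-2 direction vector (normalized internally);
#'   default is the 45 degree diagonal.
#' @return an object of class `fixed_step_model`.
#' @export
fixed_step_model <- function(total_shift, n_frames, direction = c(1, 1)) {
  if (n_frames < 2) stop("fixed_step_model requires n_frames >= 2")
  if (total_shift < 0) stop("total_shift must be >= 0")
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("direction must be a non-zero 2-vector")
  structure(list(total_shift = total_shift, n_frames = n_frames,
                 direction = direction / nrm),
            class = "fixed_step_model")
}

#' Per-frame shifts of a fixed-step model
#'
#' @param model a [fixed_step_model()].
#' @return an `n_frames` by 2 matrix of shifts in pixels; row 1 is `(0, 0)`
#'   and the last row has magnitude `total_shift`.
#' @export
fixed_step_shifts <- function(model) {
  stopifnot(inherits(model, "fixed_step_model"))
  step <- model$total_shift / (model$n_frames - 1)
  mag <- step * (0:(model$n_frames - 1))
  cbind(x = mag * model$direction[1], y = mag * model$direction[2])
}

#' Doming coefficient schedule
#'
#' Linear interpolation of the radial deformation coefficients `k1`, `k2`
#' from their start values at frame 0 to their end values at the last frame,
#' making the doming more prominent in later frames.
#'
#' @param k1_start,k1_end,k2_start,k2_end dimensionless radial coefficients.
#' @param n_frames number of frames (>= 1).
#' @return an object of class `deformation_schedule`.
#' @export
deformation_schedule <- function(k1_start = 0.01, k1_end = 0.015,
                                 k2_start = 0.01, k2_end = 0.015,
                                 n_frames = 2) {
  ks <- c(k1_start, k1_end, k2_start, k2_end)
  if (!all(is.finite(ks))) stop("deformation coefficients must be finite")
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(list(k1_start = k1_start, k1_end = k1_end,
                 k2_start = k2_start, k2_end = k2_end,
                 n_frames = n_frames),
            class = "deformation_schedule")
}

#' Interpolate the doming coefficients at a frame index
#'
#' @param schedule a [deformation_schedule()].
#' @param t frame index in `[0, n_frames - 1]`; may be a vector.
#' @return for scalar `t` a named vector `c(k1, k2)`; otherwise a matrix.
#' @export
interp_k <- function(schedule, t) {
  stopifnot(inherits(schedule, "deformation_schedule"))
  if (any(t < 0 | t > schedule$n_frames - 1)) {
    stop("frame index t outside [0, n_frames - 1]")
  }
  u <- if (schedule$n_frames == 1) rep(0, length(t)) else t / (schedule$n_frames - 1)
  k1 <- schedule$k1_start + u * (schedule$k1_end - schedule$k1_start)
  k2 <- schedule$k2_start + u * (schedule$k2_end - schedule$k2_start)
  if (length(t) == 1L) c(k1 = k1, k2 = k2) else cbind(k1 = k1, k2 = k2)
}

#' Barrel/pincushion radial transformation
#'
#' Maps a normalized radius through
#' \deqn{r_{out} = r_{in} (1 + k_1 r_{in}^2 + k_2 r_{in}^4).}
#' With positive coefficients the mapping pushes radii outward; it is the
#' identity at the origin and for vanishing coefficients.
#'
#' @param r_in normalized radius (>= 0); vectorized.
#' @param k1,k2 dimensionless coefficients.
#' @return transformed radius (same length as `r_in`).
#' @export
radial_deform <- function(r_in, k1, k2) {
  stopifnot(all(r_in >= 0))
  r_in * (1 + k1 * r_in^2 + k2 * r_in^4)
}

#' Assemble the full ground-truth motion of a movie
#'
#' Combines a global drift model (parametric, fixed-step, or none) with a
#' doming schedule into one per-frame table of shifts and radial
#' coefficients. This object is the simulator's exported truth and the
#' reference for shift-recovery scoring.
#'
#' @param n_frames number of frames.
#' @param dims frame dimensions `c(nx, ny)` in pixels.
#' @param shift a [shift_model()], a [fixed_step_model()], or `NULL` for no
#'   global drift.
#' @param doming a [deformation_schedule()], or `NULL` for no doming.
#' @return an object of class `motion_ground_truth` with per-frame `shifts`
#'   (n x 2, pixels) and `k` (n x 2), the frame `dims`, and the radius
#'   `normalization` convention tag (`"per-axis"`).
#' @export
motion_ground_truth <- function(n_frames, dims, shift = NULL, doming = NULL) {
  stopifnot(n_frames >= 1, length(dims) == 2, all(dims >= 1))
  tt <- 0:(n_frames - 1)
  shifts <- if (is.null(shift)) {
    cbind(x = rep(0, n_frames), y = rep(0, n_frames))
  } else if (inherits(shift, "shift_model")) {
    sm <- eval_shift(shift, tt)
    if (n_frames == 1L) matrix(sm, 1, 2, dimnames = list(NULL, c("x", "y"))) else sm
  } else if (inherits(shift, "fixed_step_model")) {
    if (shift$n_frames != n_frames) stop("fixed_step_model n_frames mismatch")
    fixed_step_shifts(shift)
  } else {
    stop("shift must be NULL, a shift_model or a fixed_step_model")
  }
  kmat <- if (is.null(doming)) {
    cbind(k1 = rep(0, n_frames), k2 = rep(0, n_frames))
  } else {
    if (doming$n_frames != n_frames) stop("deformation_schedule n_frames mismatch")
    km <- interp_k(doming, tt)
    if (n_frames == 1L) matrix(km, 1, 2, dimnames = list(NULL, c("k1", "k2"))) else km
  }
  structure(list(shifts = shifts, k = kmat, dims = as.integer(dims),
                 n_frames = as.integer(n_frames), normalization = "per-axis"),
            class = "motion_ground_truth")
}

#' @export
print.motion_ground_truth <- function(x, ...) {
  cat(sprintf("motion_ground_truth: %d frames, %d x %d px\n",
              x$n_frames, x$dims[1], x$dims[2]))
  last <- x$shifts[x$n_frames, ]
  cat(sprintf("  final shift (%.3f, %.3f) px; k1 %.4g -> %.4g\n",
              last[1], last[2], x$k[1, 1], x$k[x$n_frames, 1]))
  invisible(x)
}

#' Per-pixel source-coordinate map for one frame
#'
#' Composes the frame's global shift (applied first) and its radial doming
#' into the map used to render the frame: for every output pixel `p` the
#' returned coordinates point at the location in the undeformed reference
#' content that the pixel shows. Concretely,
#' `src(p) = dome(p) - s_t`, where `dome` applies [radial_deform()] about the
#' geometric frame centre in per-axis normalized coordinates (each axis mapped
#' linearly to `[-1, 1]`, so corners reach radius sqrt(2)) and `s_t` is the
#' frame's apparent content shift in pixels. A positive shift therefore moves
#' content toward +x/+y in the rendered frame, and positive `k` displaces the
#' sampled location radially outward (barrel appearance of the content).
#'
#' @param truth a [motion_ground_truth()].
#' @param t frame index, `0 .. n_frames - 1`.
#' @param dims frame dimensions; defaults to those stored in `truth`.
#' @return list with matrices `sx`, `sy` of 1-based source coordinates.
#' @export
displacement_field <- function(truth, t, dims = truth$dims) {
  stopifnot(inherits(truth, "motion_ground_truth"),
            t >= 0, t <= truth$n_frames - 1, all(dims >= 1))
  nx <- dims[1]; ny <- dims[2]
  s <- truth$shifts[t + 1, ]
  k <- truth$k[t + 1, ]
  cx <- (nx + 1) / 2
  cy <- (ny + 1) / 2
  hx <- if (nx > 1) (nx - 1) / 2 else 1
  hy <- if (ny > 1) (ny - 1) / 2 else 1
  u <- matrix((seq_len(nx) - cx) / hx, nx, ny)
  v <- matrix((seq_len(ny) - cy) / hy, nx, ny, byrow = TRUE)
  if (k[1] != 0 || k[2] != 0) {
    r2 <- u^2 + v^2
    scale <- 1 + k[1] * r2 + k[2] * r2^2
    u <- u * scale
    v <- v * scale
  }
  list(sx = cx + u * hx - s[1], sy = cy + v * hy - s[2])
}
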