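# Reference movie aligner: FFT cross-correlation with sub-pixel parabolic
# peaks, all-pairs least-squares global consensus, patch-based local motion
# with a cubic B-spline model in space and time, and micrograph synthesis.

#' Aligner configuration
#'
#' @param max_shift maximum expected shift, pixels: the cross-correlation
#'   peak search is restricted to this radius. Pairs whose peak lands on the
#'   search-window boundary are flagged as probable failures.
#' @param patch_grid local-alignment patch counts `c(px, py)`, or `"auto"`
#'   (5 x 5 for movies narrower than 5000 pixels, 7 x 5 otherwise).
#' @param reference_frame frame index (1-based) whose shift is fixed at
#'   zero, or `"middle"`.
#' @param cc_lowpass wavelength cutoff (pixels) of the Gaussian low-pass
#'   applied to correlation maps before peak search, suppressing shot noise.
#' @param interpolation micrograph-synthesis interpolation:
#'   `"bspline"` (cubic B-spline, default), `"linear"`, or `"fourier"`
#'   (phase-ramp translation; global motion only).
#' @param output_convention `"average"` (default) or `"sum"` of the aligned
#'   frames; the two differ exactly by the frame count factor.
#' @return an object of class `align_config`.
#' @export
align_config <- function(max_shift = 50, patch_grid = "auto",
                         reference_frame = "middle", cc_lowpass = 4,
                         interpolation = c("bspline", "linear", "fourier"),
                         output_convention = c("average", "sum")) {
  if (max_shift <= 0) stop("max_shift must be > 0")
  if (!identical(patch_grid, "auto")) {
    stopifnot(length(patch_grid) == 2, all(patch_grid >= 1))
  }
  structure(list(max_shift = max_shift, patch_grid = patch_grid,
                 reference_frame = reference_frame,
                 cc_lowpass = cc_lowpass,
                 interpolation = match.arg(interpolation),
                 output_convention = match.arg(output_convention)),
            class = "align_config")
}

.stack_data <- function(frames) {
  if (inherits(frames, "frame_stack")) frames$data else frames
}

# Wrapped integer shift values of each FFT index.
.wrapped_shifts <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

# Core peak search on a cross-power spectrum. Returns the sub-pixel shift of
# b relative to a, the peak height, and a boundary flag.
.cc_peak <- function(cross, nx, ny, max_shift, cc_lowpass) {
  if (cc_lowpass > 0) {
    g <- freq_grid(nx, ny)
    fc <- 1 / cc_lowpass
    cross <- cross * exp(-log(2) * ((g$fx^2 + g$fy^2) / fc^2))
  }
  cc <- Re(stats::fft(cross, inverse = TRUE)) / (nx * ny)
  sxv <- .wrapped_shifts(nx)
  syv <- .wrapped_shifts(ny)
  ok <- outer(abs(sxv) <= max_shift, abs(syv) <= max_shift)
  ccm <- cc
  ccm[!ok] <- -Inf
  peak <- max(ccm)
  idx <- which(ccm == peak)
  if (length(idx) > 1) {  # break ties toward the smaller shift
    ij <- arrayInd(idx, dim(ccm))
    mag <- abs(sxv[ij[, 1]]) + abs(syv[ij[, 2]])
    idx <- idx[which.min(mag)]
  }
  ij <- arrayInd(idx, dim(ccm))
  i <- ij[1]; j <- ij[2]
  wrap <- function(v, n) ((v - 1) %% n) + 1
  para <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (is.finite(den) && den < 0) {
      max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
    } else 0
  }
  dx <- para(cc[wrap(i - 1, nx), j], cc[i, j], cc[wrap(i + 1, nx), j])
  dy <- para(cc[i, wrap(j - 1, ny)], cc[i, j], cc[i, wrap(j + 1, ny)])
  shift <- c(sxv[i] + dx, syv[j] + dy)
  flagged <- max(abs(shift)) >= max_shift - 0.5
  list(shift = shift, peak = peak, flagged = flagged)
}

#' Sub-pixel shift between two frames by cross-correlation
#'
#' FFT cross-correlation of the mean-subtracted frames, low-pass filtered,
#' with the peak search restricted to `+/- max_shift` and the integer peak
#' refined by a 1-D parabola per axis over its 3 x 3 neighbourhood.
#'
#' @param frame_a,frame_b numeric matrices of equal dimensions.
#' @param max_shift search radius, pixels (`< min(dim)/4`).
#' @param cc_lowpass correlation-map low-pass wavelength, pixels (0 = off).
#' @return length-2 numeric vector: shift of `frame_b` relative to
#'   `frame_a` in pixels (positive means the content of `b` sits at larger
#'   x/y than in `a`), with attributes `peak` and `flagged`.
#' @export
cc_shift_pair <- function(frame_a, frame_b, max_shift = 50, cc_lowpass = 4) {
  stopifnot(all(dim(frame_a) == dim(frame_b)))
  nx <- nrow(frame_a); ny <- ncol(frame_a)
  if (max_shift >= min(nx, ny) / 4) {
    stop("max_shift must be < min(dims)/4")
  }
  if (sd(frame_a) == 0 || sd(frame_b) == 0) {
    stop("degenerate input: zero-variance frame gives a flat correlation surface")
  }
  Fa <- stats::fft(frame_a - mean(frame_a))
  Fb <- stats::fft(frame_b - mean(frame_b))
  res <- .cc_peak(Conj(Fa) * Fb, nx, ny, max_shift, cc_lowpass)
  structure(res$shift, peak = res$peak, flagged = res$flagged)
}

.resolve_reference <- function(reference_frame, nt) {
  if (identical(reference_frame, "middle")) (nt + 1L) %/% 2L
  else as.integer(reference_frame)
}

#' Global movie alignment
#'
#' Measures the pairwise shift of every frame pair `(i < j)` by
#' [cc_shift_pair()], then solves the overdetermined system
#' `s_j - s_i = d_ij` for the per-frame shifts by least squares with the
#' reference frame fixed at zero. Pairs whose correlation peak lies on the
#' search-window boundary, or whose measurement is grossly inconsistent with
#' the consensus solution (periodic content can produce confident aliased
#' peaks inside the window), are flagged and excluded from the solve; if
#' more than half of all pairs end up flagged the alignment is declared
#' failed -- the signature of a `max_shift` bound smaller than the true
#' drift.
#'
#' @param frames a [frame_stack()] or 3-D array with >= 2 frames.
#' @param cfg an [align_config()].
#' @param consistency_tol pairwise residual (pixels) beyond which a
#'   measurement is considered inconsistent with the consensus solution.
#' @return an object of class `global_alignment`: per-frame `shifts`
#'   (n x 2, pixels, reference row exactly zero), `reference_frame`,
#'   `residual` (RMS of pairwise fit residuals), `flagged_fraction`.
#' @export
solve_global <- function(frames, cfg = align_config(), consistency_tol = 2) {
  data <- .stack_data(frames)
  d <- dim(data)
  nt <- d[3]
  if (nt < 2) stop("need at least 2 frames")
  if (cfg$max_shift >= min(d[1], d[2]) / 4) {
    stop("max_shift must be < min(dims)/4")
  }
  ffts <- vector("list", nt)
  for (t in seq_len(nt)) {
    fr <- data[, , t]
    if (sd(fr) == 0) stop("degenerate input: zero-variance frame")
    ffts[[t]] <- stats::fft(fr - mean(fr))
  }
  pairs <- which(upper.tri(matrix(0, nt, nt)), arr.ind = TRUE)
  np <- nrow(pairs)
  meas <- matrix(0, np, 2)
  flagged <- logical(np)
  for (p in seq_len(np)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    res <- .cc_peak(Conj(ffts[[i]]) * ffts[[j]], d[1], d[2],
                    cfg$max_shift, cfg$cc_lowpass)
    meas[p, ] <- res$shift
    flagged[p] <- res$flagged
  }
  ref <- .resolve_reference(cfg$reference_frame, nt)
  Afull <- matrix(0, np, nt)
  for (r in seq_len(np)) {
    Afull[r, pairs[r, 1]] <- -1
    Afull[r, pairs[r, 2]] <- 1
  }
  Afull <- Afull[, -ref, drop = FALSE]

  # Iterative consensus: solve, then flag pairs grossly inconsistent with the
  # least-squares solution (periodic content can yield confident but aliased
  # peaks well inside the search window) and refit without them.
  keep <- !flagged
  sol <- NULL
  for (it in 1:5) {
    if (mean(!keep) > 0.5) break
    A <- Afull[keep, , drop = FALSE]
    sol <- .ls_minnorm(A, meas[keep, , drop = FALSE])
    resid_all <- Afull %*% sol - meas
    bad <- apply(abs(resid_all), 1, max) > consistency_tol
    new_keep <- !flagged & !bad
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  frac <- mean(!keep)
  if (frac > 0.5) {
    stop(sprintf(paste0("alignment failure: %.0f%% of frame pairs hit the ",
                        "max_shift search bound (%g px) or disagree with the ",
                        "consensus; increase max_shift"),
                 100 * frac, cfg$max_shift))
  }
  shifts <- matrix(0, nt, 2, dimnames = list(NULL, c("x", "y")))
  shifts[-ref, ] <- sol
  resid <- Afull[keep, , drop = FALSE] %*% sol - meas[keep, , drop = FALSE]
  if (any(sqrt(rowSums(shifts^2)) > cfg$max_shift + 0.5)) {
    warning("some per-frame shifts exceed max_shift after consensus")
  }
  structure(list(shifts = shifts, reference_frame = ref,
                 residual = sqrt(mean(resid^2)),
                 flagged_fraction = frac, max_shift = cfg$max_shift),
            class = "global_alignment")
}

#' @export
print.global_alignment <- function(x, ...) {
  cat(sprintf("global_alignment: %d frames, reference %d, pair residual %.3g px\n",
              nrow(x$shifts), x$reference_frame, x$residual))
  invisible(x)
}

#' Treat a ground-truth trajectory as a global alignment
#'
#' Re-references the true per-frame shifts to a chosen reference frame so
#' they can drive [render_micrograph()] or serve as a perfect-alignment
#' baseline.
#'
#' @param truth a [motion_ground_truth()].
#' @param reference_frame frame index or `"middle"`.
#' @return a `global_alignment`.
#' @export
as_global_alignment <- function(truth, reference_frame = "middle") {
  stopifnot(inherits(truth, "motion_ground_truth"))
  ref <- .resolve_reference(reference_frame, truth$n_frames)
  shifts <- sweep(truth$shifts, 2, truth$shifts[ref, ])
  colnames(shifts) <- c("x", "y")
  structure(list(shifts = shifts, reference_frame = ref,
                 residual = 0, flagged_fraction = 0, max_shift = Inf),
            class = "global_alignment")
}

# Tensor-product cubic B-spline basis helpers. Bases are built once with
# boundary knots covering the full frame (and movie duration) so evaluation
# anywhere in the movie never extrapolates.
.make_basis_spec <- function(values, df, boundary) {
  B <- splines::bs(values, df = df, degree = 3, intercept = TRUE,
                   Boundary.knots = boundary)
  list(knots = attr(B, "knots"), boundary = boundary, df = df)
}

.eval_basis <- function(values, spec) {
  splines::bs(values, knots = spec$knots, degree = 3, intercept = TRUE,
              Boundary.knots = spec$boundary)
}

# Minimum-norm least squares via SVD (the tensor design is typically
# rank-deficient: more coefficients than patch observations).
.ls_minnorm <- function(M, y) {
  sv <- svd(M)
  tol <- max(dim(M)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
}

#' Patch-based local alignment
#'
#' Divides the globally compensated frames into a patch grid, measures each
#' patch's residual shift per frame against the patch's temporal average by
#' cross-correlation, and fits a cubic B-spline motion model over space and
#' time to all patch shifts.
#'
#' @param frames a [frame_stack()] or 3-D array.
#' @param global a `global_alignment` from [solve_global()] (or
#'   [as_global_alignment()]).
#' @param cfg an [align_config()]; `patch_grid = "auto"` selects 5 x 5 below
#'   5000 pixels width and 7 x 5 above. Patches must be at least 128 pixels.
#' @return an object of class `local_motion_model`: patch `centers`,
#'   per-patch per-frame `shifts` (`[patch, frame, 2]`), the spline
#'   coefficient grid, and `fit_rmse` (pixels).
#' @export
local_align <- function(frames, global, cfg = align_config()) {
  data <- .stack_data(frames)
  d <- dim(data)
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  stopifnot(inherits(global, "global_alignment"), nrow(global$shifts) == nt)

  grid <- cfg$patch_grid
  if (identical(grid, "auto")) grid <- if (nx < 5000) c(5, 5) else c(7, 5)
  gx <- grid[1]; gy <- grid[2]
  pw <- nx %/% gx
  ph <- ny %/% gy
  if (min(pw, ph) < 128) {
    stop(sprintf("patch size %d x %d px below the 128 px minimum; use a coarser grid",
                 pw, ph))
  }

  # Compensate the estimated global motion (bicubic gather at p + s_t).
  comp <- array(0, d)
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  for (t in seq_len(nt)) {
    s <- global$shifts[t, ]
    if (all(s == 0)) {
      comp[, , t] <- data[, , t]
    } else {
      comp[, , t] <- warp_image(data[, , t], X + s[1], Y + s[2],
                                method = "bicubic", fill = mean(data[, , t]))
    }
  }

  x0 <- round(seq(1, nx - pw + 1, length.out = gx))
  y0 <- round(seq(1, ny - ph + 1, length.out = gy))
  centers <- expand.grid(cx = x0 + (pw - 1) / 2, cy = y0 + (ph - 1) / 2)
  npatch <- nrow(centers)
  patch_ms <- min(cfg$max_shift, floor(min(pw, ph) / 4) - 1)

  shifts <- array(0, c(npatch, nt, 2))
  p <- 0
  for (jy in seq_len(gy)) {
    for (ix in seq_len(gx)) {
      p <- p + 1
      xs <- x0[ix]:(x0[ix] + pw - 1)
      ys <- y0[jy]:(y0[jy] + ph - 1)
      stackp <- comp[xs, ys, , drop = FALSE]
      refp <- apply(stackp, 1:2, mean)
      for (t in seq_len(nt)) {
        shifts[p, t, ] <- cc_shift_pair(refp, stackp[, , t],
                                        max_shift = patch_ms,
                                        cc_lowpass = cfg$cc_lowpass)
      }
    }
  }
  # patches are laid out with x varying fastest, matching expand.grid above

  bx <- .make_basis_spec(centers$cx, df = gx + 3, boundary = c(1, nx))
  by <- .make_basis_spec(centers$cy, df = gy + 3, boundary = c(1, ny))
  bt <- .make_basis_spec(seq_len(nt), df = max(4, nt %/% 2), boundary = c(1, nt))

  obs_x <- rep(centers$cx, times = nt)
  obs_y <- rep(centers$cy, times = nt)
  obs_t <- rep(seq_len(nt), each = npatch)
  Bx <- .eval_basis(obs_x, bx)
  By <- .eval_basis(obs_y, by)
  Bt <- .eval_basis(obs_t, bt)
  idx <- expand.grid(a = seq_len(ncol(Bx)), b = seq_len(ncol(By)),
                     c = seq_len(ncol(Bt)))
  M <- Bx[, idx$a] * By[, idx$b] * Bt[, idx$c]
  yx <- as.vector(shifts[, , 1])
  yy <- as.vector(shifts[, , 2])
  coef <- .ls_minnorm(M, cbind(yx, yy))
  pred <- M %*% coef
  fit_rmse <- sqrt(mean((pred - cbind(yx, yy))^2))

  structure(list(centers = centers, shifts = shifts, grid = c(gx, gy),
                 patch_size = c(pw, ph),
                 basis = list(x = bx, y = by, t = bt),
                 coef = coef, fit_rmse = fit_rmse),
            class = "local_motion_model")
}

#' @export
print.local_motion_model <- function(x, ...) {
  cat(sprintf("local_motion_model: %d x %d patches (%d x %d px), fit RMSE %.3g px\n",
              x$grid[1], x$grid[2], x$patch_size[1], x$patch_size[2],
              x$fit_rmse))
  invisible(x)
}

#' Evaluate the local motion model
#'
#' @param local a `local_motion_model`.
#' @param x,y pixel coordinates (vectors of equal length).
#' @param t frame index (1-based scalar).
#' @return matrix with columns `dx`, `dy`: residual shift in pixels.
#' @export
predict_local <- function(local, x, y, t) {
  stopifnot(inherits(local, "local_motion_model"), length(t) == 1)
  Bx <- .eval_basis(x, local$basis$x)
  By <- .eval_basis(y, local$basis$y)
  Bt <- .eval_basis(t, local$basis$t)
  ka <- ncol(Bx); kb <- ncol(By); kc <- ncol(Bt)
  out <- matrix(0, length(x), 2, dimnames = list(NULL, c("dx", "dy")))
  for (comp in 1:2) {
    C3 <- array(local$coef[, comp], c(ka, kb, kc))
    At <- matrix(0, ka, kb)
    for (cc in seq_len(kc)) At <- At + C3[, , cc] * Bt[1, cc]
    out[, comp] <- rowSums((Bx %*% At) * By)
  }
  out
}

# Displacement surfaces (dx, dy) over the whole frame for frame t.
.local_field <- function(local, nx, ny, t) {
  Bx <- .eval_basis(seq_len(nx), local$basis$x)
  By <- .eval_basis(seq_len(ny), local$basis$y)
  Bt <- .eval_basis(t, local$basis$t)
  ka <- ncol(Bx); kb <- ncol(By); kc <- ncol(Bt)
  fields <- list()
  for (comp in 1:2) {
    C3 <- array(local$coef[, comp], c(ka, kb, kc))
    At <- matrix(0, ka, kb)
    for (cc in seq_len(kc)) At <- At + C3[, , cc] * Bt[1, cc]
    fields[[comp]] <- Bx %*% At %*% t(By)
  }
  names(fields) <- c("dx", "dy")
  fields
}

#' Synthesize the aligned micrograph
#'
#' Warps each frame by the inverse of its estimated motion (global shift
#' plus, optionally, the local residual field) and combines the aligned
#' frames by average or sum.
#'
#' @param frames a [frame_stack()] or 3-D array.
#' @param global a `global_alignment`.
#' @param local optional `local_motion_model`.
#' @param cfg an [align_config()]; its `interpolation` and
#'   `output_convention` control the synthesis. `"fourier"` interpolation
#'   supports global motion only.
#' @return numeric matrix: the micrograph.
#' @export
render_micrograph <- function(frames, global, local = NULL,
                              cfg = align_config()) {
  data <- .stack_data(frames)
  d <- dim(data)
  nx <- d[1]; ny <- d[2]; nt <- d[3]
  stopifnot(inherits(global, "global_alignment"), nrow(global$shifts) == nt)
  interp <- cfg$interpolation
  if (interp == "fourier" && !is.null(local)) {
    stop("fourier interpolation supports global motion only")
  }
  X <- matrix(seq_len(nx), nx, ny)
  Y <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  acc <- matrix(0, nx, ny)
  for (t in seq_len(nt)) {
    s <- global$shifts[t, ]
    fr <- data[, , t]
    if (interp == "fourier") {
      acc <- acc + translate_fourier(fr, s[1], s[2])
      next
    }
    sx <- X + s[1]
    sy <- Y + s[2]
    if (!is.null(local)) {
      lf <- .local_field(local, nx, ny, t)
      sx <- sx + lf$dx
      sy <- sy + lf$dy
    }
    if (all(s == 0) && is.null(local)) {
      acc <- acc + fr
    } else {
      meth <- if (interp == "linear") "bilinear" else "bspline"
      acc <- acc + warp_image(fr, sx, sy, method = meth, fill = mean(fr))
    }
  }
  if (cfg$output_convention == "average") acc / nt else acc
}
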