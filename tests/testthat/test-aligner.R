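# Reference aligner: pairwise cross-correlation, global consensus, local
# patch motion with the space-time B-spline model, micrograph synthesis.

test_that("cross-correlation recovers exact and sub-pixel shifts", {
  img <- smooth_field(128, seed = 2)
  expect_equal(cc_shift_pair(img, img, max_shift = 20), c(0, 0),
               ignore_attr = TRUE)

  # circular shift: the correlation surface is exactly symmetric about the
  # peak, so the parabolic refinement returns the integer shift exactly
  shifted <- img[c(124:128, 1:123), c(126:128, 1:125)]  # content moves +5, +3
  expect_equal(cc_shift_pair(img, shifted, max_shift = 20), c(5, 3),
               tolerance = 1e-9, ignore_attr = TRUE)

  # Fourier-shifted copy: sub-pixel accuracy within 0.1 px
  sub <- cryophantom:::translate_fourier(img, -2.5, 0)
  est <- cc_shift_pair(img, sub, max_shift = 20)
  expect_lt(abs(est[1] - 2.5), 0.1)
  expect_lt(abs(est[2]), 0.1)

  expect_error(cc_shift_pair(matrix(1, 32, 32), img[1:32, 1:32], max_shift = 5),
               "degenerate")
  expect_error(cc_shift_pair(img, img, max_shift = 64), "max_shift")
})

test_that("global alignment recovers fixed-step drift on noiseless movies", {
  mv <- fixed_step_movie(dims = c(256, 256), n_frames = 10, total = 10,
                         grid_step = 64, seed = 3)
  ga <- solve_global(mv$frames, align_config(max_shift = 20))
  expect_equal(unname(ga$shifts[ga$reference_frame, ]), c(0, 0))
  expect_lt(shift_rmse(ga, mv$truth), 0.2)

  # identical frames give all-zero shifts
  const_mv <- array(rep(smooth_field(64, seed = 4), 3), c(64, 64, 3))
  ga0 <- solve_global(const_mv, align_config(max_shift = 10))
  expect_lt(max(abs(ga0$shifts)), 1e-9)
})

test_that("pairwise measurements are transitive on noiseless input", {
  mv <- fixed_step_movie(dims = c(256, 256), n_frames = 3, total = 4,
                         grid_step = 64, seed = 5)
  d <- mv$frames$data
  s01 <- cc_shift_pair(d[, , 1], d[, , 2], max_shift = 20)
  s12 <- cc_shift_pair(d[, , 2], d[, , 3], max_shift = 20)
  s02 <- cc_shift_pair(d[, , 1], d[, , 3], max_shift = 20)
  expect_lt(max(abs(s02 - (s01 + s12))), 0.3)
})

test_that("a too-small max_shift bound fails loudly and a larger one succeeds", {
  spec <- phantom_spec(c(640, 640), 8, ice = ice_spec(), seed = 31)
  mv <- simulate_movie(spec,
                       shift = fixed_step_model(120, 8, direction = c(1, 0)))
  expect_error(solve_global(mv$frames, align_config(max_shift = 50)),
               "alignment failure")
  ga <- solve_global(mv$frames, align_config(max_shift = 150))
  expect_lt(shift_rmse(ga, mv$truth), 0.2)
})

test_that("local model is near zero for purely global motion", {
  mv <- fixed_step_movie(dims = c(512, 512), n_frames = 6, total = 6,
                         grid_step = 150, ice = ice_spec(), seed = 7)
  cfg <- align_config(max_shift = 20, patch_grid = c(3, 3))
  ga <- solve_global(mv$frames, cfg)
  la <- local_align(mv$frames, ga, cfg)
  expect_lt(max(abs(la$shifts)), 0.3)

  # spline evaluated at the patch centres reproduces the fitted shifts
  for (t in c(1, 4, 6)) {
    pred <- predict_local(la, la$centers$cx, la$centers$cy, t)
    expect_lt(max(abs(pred - la$shifts[, t, ])), 0.1)
  }

  expect_error(local_align(mv$frames, ga,
                           align_config(patch_grid = c(8, 8))),
               "patch")
})

test_that("doming leaves larger patch residuals at the corners than the centre", {
  spec <- phantom_spec(c(512, 512), 8, ice = ice_spec(), seed = 23)
  mv <- simulate_movie(spec, doming = deformation_schedule(n_frames = 8))
  cfg <- align_config(max_shift = 20, patch_grid = c(3, 3))
  ga <- solve_global(mv$frames, cfg)
  la <- local_align(mv$frames, ga, cfg)
  mag <- sqrt(la$shifts[, , 1]^2 + la$shifts[, , 2]^2)
  per_patch <- matrix(rowMeans(mag), 3, 3)
  corner <- mean(per_patch[c(1, 3), c(1, 3)])
  centre <- per_patch[2, 2]
  expect_gt(corner, centre)
})

test_that("micrograph synthesis honours motion and output conventions", {
  # zero motion, average convention: micrograph is the frame mean
  set.seed(11)
  stack <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  tr0 <- motion_ground_truth(4, c(32, 32))
  ga0 <- as_global_alignment(tr0)
  mic <- render_micrograph(stack, ga0, cfg = align_config())
  expect_equal(mic, apply(stack, 1:2, mean))

  # sum = average * n_frames
  mic_sum <- render_micrograph(stack, ga0,
                               cfg = align_config(output_convention = "sum"))
  expect_equal(mic_sum, mic * 4, tolerance = 1e-6)

  # constant movie: average equals the constant, sum equals n * constant
  cst <- array(2.5, c(32, 32, 5))
  ga5 <- as_global_alignment(motion_ground_truth(5, c(32, 32)))
  expect_true(all(render_micrograph(cst, ga5, cfg = align_config()) == 2.5))
  expect_true(all(render_micrograph(cst, ga5,
                  cfg = align_config(output_convention = "sum")) == 12.5))

  expect_error(render_micrograph(stack, ga0, local = structure(list(),
                 class = "local_motion_model"),
                 cfg = align_config(interpolation = "fourier")),
               "fourier")
})

test_that("aligning with true shifts restores grid-line sharpness", {
  mv <- fixed_step_movie(dims = c(256, 256), n_frames = 6, total = 6,
                         grid_step = 64, seed = 13)
  base <- render_signal(phantom_spec(c(256, 256), 1, grid_step = 64,
                                     line_width = 5))
  ga <- as_global_alignment(mv$truth)
  mic <- render_micrograph(mv$frames, ga, cfg = align_config())
  # edge profile across a vertical grid line, away from the frame border:
  # width (pixels above half-maximum) within 1 px of the unmoved signal
  line_profile <- function(img) {
    pr <- img[129:160, 128]
    sum(pr > (max(pr) + min(pr)) / 2)
  }
  expect_lte(abs(line_profile(mic) - line_profile(base)), 1)
})

test_that("linear interpolation damps high frequencies more than B-spline", {
  spec <- phantom_spec(c(256, 256), 8, ice = ice_spec(), seed = 21)
  mv <- simulate_movie(spec, shift = fixed_step_model(7.3, 8))
  ga <- as_global_alignment(mv$truth)
  mic_b <- render_micrograph(mv$frames, ga, cfg = align_config())
  mic_l <- render_micrograph(mv$frames, ga,
                             cfg = align_config(interpolation = "linear"))
  pb <- radial_psd(mic_b)
  pl <- radial_psd(mic_l)
  band <- pb$freq >= 0.9 * 0.5  # top 10% of the frequency range
  expect_lt(mean(pl$power[band]), mean(pb$power[band]))
})
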