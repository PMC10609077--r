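# Phantom synthesis: signal patterns, simulated ice, deterministic frame
# rendering, Poisson dose, gain/dark references.

test_that("grid signal matches a brute-force pixel classification", {
  spec <- phantom_spec(c(300, 300), 1, grid_step = 150, line_width = 5)
  sig <- render_signal(spec)
  # brute force: a pixel is on a line iff its 0-based coordinate modulo the
  # step falls inside [0, line_width)
  brute <- matrix(0, 300, 300)
  for (ix in 1:300) {
    for (iy in 1:300) {
      if (((ix - 1) %% 150) < 5 || ((iy - 1) %% 150) < 5) brute[ix, iy] <- 1
    }
  }
  expect_identical(sig, brute)
  # line positions: 0-based columns 0 and 150 within a 300 px frame
  on_cols <- which(apply(sig, 1, function(col) all(col > 0))) - 1
  expect_equal(on_cols, c(0:4, 150:154))
})

test_that("invalid signal geometry is rejected", {
  expect_error(phantom_spec(c(64, 64), 1, line_width = 0), "line_width")
  expect_error(phantom_spec(c(64, 64), 1, grid_step = 5, line_width = 5),
               "grid_step")
  expect_error(phantom_spec(c(8, 8), 1), "dims")
})

test_that("a centred disc covers ~ pi r^2 pixels", {
  spec <- phantom_spec(c(300, 300), 1, signal = "disc", disc_radius = 50,
                       disc_layout = "center")
  sig <- render_signal(spec)
  expect_lt(abs(sum(sig > 0) - pi * 50^2) / (pi * 50^2), 0.02)
})

test_that("cross signal is a centred plus sign of the configured width", {
  spec <- phantom_spec(c(101, 101), 1, signal = "cross", line_width = 5,
                       cross_arm = 30)
  sig <- render_signal(spec)
  expect_gt(sig[51, 51], 0)     # centre on
  expect_gt(sig[51, 25], 0)     # on the vertical arm
  expect_equal(sig[51, 15], 0)  # beyond the arm
  expect_equal(sig[10, 10], 0)  # off-axis
})

test_that("simulated ice respects range, seed determinism and band limits", {
  ice1 <- simulate_ice(c(128, 128), ice_spec(), pixel_size = 1, seed = 7)
  ice2 <- simulate_ice(c(128, 128), ice_spec(), pixel_size = 1, seed = 7)
  expect_identical(ice1, ice2)
  expect_equal(min(ice1), 0)
  expect_equal(max(ice1), 2)

  # spectral leakage: power above the cutoff vs power at half-cutoff
  P <- Mod(stats::fft(ice1 - mean(ice1)))^2
  g <- cryophantom:::freq_grid(128, 128)
  f <- sqrt(g$fx^2 + g$fy^2)
  cutoff <- 1 / 3
  above <- mean(P[f > cutoff])
  at_half <- mean(P[abs(f - cutoff / 2) < 0.02])
  expect_lt(above, 0.01 * at_half)

  expect_error(simulate_ice(c(64, 64), ice_spec(lowpass_resolution = 1.5)),
               "Nyquist")
})

test_that("deterministic frames reproduce exactly and respect zero motion", {
  spec <- phantom_spec(c(64, 64), 3, grid_step = 32, ice = ice_spec(), seed = 5)
  tr <- motion_ground_truth(3, c(64, 64))
  f1 <- render_movie(spec, tr)
  f2 <- render_movie(spec, tr)
  expect_identical(f1$data, f2$data)
  # zero motion: every frame equals ice + signal exactly
  base <- render_signal(spec) + simulate_ice(c(64, 64), ice_spec(), seed = 5)
  for (t in 1:3) expect_equal(f1$data[, , t], base)
})

test_that("rendered frames carry the ground-truth shifts", {
  mv <- fixed_step_movie(dims = c(128, 128), n_frames = 4, total = 5,
                         direction = c(1, 0), grid_step = 50,
                         ice = ice_spec(), seed = 13)
  for (t in 2:4) {
    est <- cc_shift_pair(mv$frames$data[, , 1], mv$frames$data[, , t],
                         max_shift = 10)
    expect_lt(max(abs(est - mv$truth$shifts[t, ])), 0.1)
  }
})

test_that("doming preserves the centre better than the corners", {
  spec <- phantom_spec(c(256, 256), 8, grid_step = 64, ice = ice_spec(),
                       seed = 17)
  mv <- simulate_movie(spec, doming = deformation_schedule(n_frames = 8))
  first <- mv$frames$data[, , 1]
  last <- mv$frames$data[, , 8]
  ctr <- 97:160   # central 64 px window
  cnr <- 1:64     # corner window
  cor_center <- cor(as.vector(first[ctr, ctr]), as.vector(last[ctr, ctr]))
  cor_corner <- cor(as.vector(first[cnr, cnr]), as.vector(last[cnr, cnr]))
  expect_gt(cor_center, cor_corner)
})

test_that("Poisson dose has the right moments, determinism and edge cases", {
  fs <- frame_stack(matrix(4, 256, 256))
  d1 <- apply_dose(fs, seed = 5)
  d2 <- apply_dose(fs, seed = 5)
  expect_identical(d1$data, d2$data)
  n <- length(d1$data)
  expect_lt(abs(mean(d1$data) - 4), 3 * sqrt(4 / n))
  # var(sample variance) ~ (mu4 - sigma^4)/n with Poisson mu4 = lambda(1+3*lambda)
  expect_lt(abs(var(as.vector(d1$data)) - 4), 3 * sqrt((4 * 13 - 16) / n))

  z <- apply_dose(frame_stack(matrix(0, 8, 8)), seed = 1)
  expect_true(all(z$data == 0))

  neg <- frame_stack(matrix(c(-1, rep(1, 63)), 8, 8))
  expect_message(dneg <- apply_dose(neg, seed = 2), "clipped")
  expect_identical(attr(dneg, "clipped"), 1L)
  expect_true(all(dneg$data >= 0))
})

test_that("dose replicates average back to the deterministic frame", {
  spec <- phantom_spec(c(64, 64), 1, grid_step = 32, ice = ice_spec(), seed = 19)
  det <- render_movie(spec, motion_ground_truth(1, c(64, 64)))$data[, , 1]
  R <- 200
  acc <- matrix(0, 64, 64)
  for (r in seq_len(R)) {
    acc <- acc + apply_dose(frame_stack(det), seed = 1000 + r)$data[, , 1]
  }
  avg <- acc / R
  # per-pixel standard error is sqrt(lambda/R); allow a generous max-norm band
  expect_lt(max(abs(avg - det)), 6 * sqrt(max(det) / R))
  expect_lt(mean(abs(avg - det)), 2 * sqrt(mean(det) / R))
})

test_that("gain and dark references are flat at movie dimensions", {
  gd <- generate_gain_dark(c(32, 48))
  expect_equal(sum(gd$gain), 32 * 48)
  expect_equal(sum(gd$dark), 0)
  gd1 <- generate_gain_dark(c(1, 1))
  expect_equal(gd1$gain, matrix(1, 1, 1))
  expect_equal(gd1$dark, matrix(0, 1, 1))
  # round-trip through MRC preserves the references exactly
  tmp_g <- tempfile(fileext = ".mrc")
  write_mrc(gd$gain, tmp_g)
  expect_equal(read_mrc(tmp_g)$data[, , 1], gd$gain)
  unlink(tmp_g)
})
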