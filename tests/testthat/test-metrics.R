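# Quality metrics: window triplets, trimmed CV, radial PSD, PSD-drop
# resolution limit, shift-recovery RMSE.

test_that("window triplet offsets follow the corner/centre/corner rule", {
  img <- matrix(rnorm(1024 * 1024), 1024, 1024)
  w <- extract_windows(img)
  expect_equal(unname(w$offsets["top_left", ]), c(0, 0))
  expect_equal(unname(w$offsets["center", ]), c(256, 256))
  expect_equal(unname(w$offsets["bottom_right", ]), c(512, 512))
  expect_equal(dim(w$center), c(512, 512))
  expect_equal(mean(w$center_normalized), 0, tolerance = 1e-12)
  expect_equal(sd(w$center_normalized), 1, tolerance = 1e-12)

  # degenerate case: a 512 px image yields three identical windows
  img2 <- img[1:512, 1:512]
  w2 <- extract_windows(img2)
  expect_identical(w2$top_left, w2$center)
  expect_identical(w2$center, w2$bottom_right)

  expect_error(extract_windows(img[1:100, ]), "window")
  expect_error(extract_windows(matrix(1, 512, 512)), "degenerate")
})

test_that("window offsets stay in bounds across a range of sizes", {
  for (n in c(512, 513, 700, 1023, 1301)) {
    img <- matrix(0, n, n)
    img[1, 1] <- 1  # avoid the degenerate constant centre only if needed
    img[n %/% 2, n %/% 2] <- 2
    w <- extract_windows(img)
    expect_true(all(w$offsets >= 0))
    expect_true(all(w$offsets + 512 <= n))
  }
})

test_that("trimmed CV matches a brute-force computation and resists outliers", {
  expect_equal(histogram_cv(matrix(5, 10, 10))$cv, 0)

  v <- 1:100
  got <- histogram_cv(v)
  q <- quantile(v, c(0.1, 0.9), names = FALSE)
  iqr <- q[2] - q[1]
  keep <- v >= q[1] - 1.5 * iqr & v <= q[2] + 1.5 * iqr
  expect_equal(got$cv, 100 * sd(v[keep]) / mean(v[keep]))
  expect_equal(got$n_trimmed, sum(!keep))

  # one extreme outlier moves the trimmed CV by less than 1% relative
  v_out <- c(v, 1e6)
  expect_lt(abs(histogram_cv(v_out)$cv - got$cv) / got$cv, 0.01)

  # the raw histogram is computed before any trimming or normalization
  expect_equal(sum(got$histogram$counts), 100)
  expect_error(histogram_cv(c(-1, 1)), "CV")
})

test_that("radial PSD has the expected structure on reference inputs", {
  # constant image: all power at DC
  p0 <- radial_psd(matrix(3, 64, 64))
  expect_gt(p0$power[1], 0)
  expect_true(all(p0$power[-1] <= 1e-12 * p0$power[1]))

  # white noise: flat non-DC profile (relative sd of bin means below 10%)
  set.seed(31)
  pw <- radial_psd(matrix(rnorm(256 * 256), 256, 256))
  flat <- pw$power[pw$freq > 0.03]
  expect_lt(sd(flat) / mean(flat), 0.10)

  # Parseval: full-plane bin totals sum to the image energy
  img <- smooth_field(64, seed = 33)
  p <- radial_psd(img)
  expect_equal(sum(attr(p, "total_power_by_bin")), attr(p, "energy"),
               tolerance = 1e-6)

  # transposition invariance for square images
  pt <- radial_psd(t(img))
  expect_equal(p$power, pt$power, tolerance = 1e-9)

  expect_error(radial_psd(matrix(1, 32, 32)), "64")
})

test_that("PSD-drop resolution limit handles crossings, fallback, and blur", {
  # synthetic profile crossing 1/100 of DC at 0.2 cycles/px -> 5 A at 1 A/px
  psd <- data.frame(freq = seq(0, 0.5, by = 0.05),
                    power = c(100, 80, 60, 40, 0.5, 0.4, rep(0.3, 5)))
  expect_equal(psd_resolution_limit(psd, pixel_size = 1), 5)

  # a profile that never drops below the threshold falls back to Nyquist
  flat <- data.frame(freq = seq(0, 0.5, by = 0.1), power = rep(10, 6))
  expect_equal(psd_resolution_limit(flat, pixel_size = 1), 2)
  expect_equal(psd_resolution_limit(flat, pixel_size = 0.6), 1.2)

  expect_error(psd_resolution_limit(data.frame(freq = c(0.1, 0.2),
                                               power = c(1, 1))), "DC")

  # Gaussian blur of increasing width never improves the resolution limit
  mv <- fixed_step_movie(dims = c(256, 256), n_frames = 4, total = 3,
                         ice = ice_spec(), grid_step = 64, seed = 21)
  mic <- render_micrograph(mv$frames, as_global_alignment(mv$truth),
                           cfg = align_config())
  res <- sapply(c(0, 1, 2, 3), function(s) {
    m <- if (s == 0) mic else cryophantom:::fft_gaussian_blur(mic, s)
    psd_resolution_limit(radial_psd(m), reference = "first")
  })
  expect_true(all(diff(res) >= 0))
})

test_that("shift RMSE is gauge-invariant and matches closed forms", {
  tr <- motion_ground_truth(10, c(64, 64),
                            shift = fixed_step_model(5, 10))
  est <- as_global_alignment(tr, reference_frame = 3)
  expect_equal(shift_rmse(est, tr), 0)

  # constant offset is gauge, not error
  off <- est
  off$shifts <- est$shifts + 2
  expect_equal(shift_rmse(off, tr), 0)

  # +1 px in x on every non-reference frame: RMSE = sqrt((n-1)/n)
  n <- 10
  bump <- est
  bump$shifts[, 1] <- bump$shifts[, 1] + 1
  bump$shifts[3, 1] <- bump$shifts[3, 1] - 1
  expect_equal(shift_rmse(bump, tr), sqrt((n - 1) / n))

  expect_error(shift_rmse(est$shifts[1:5, ], tr), "mismatch")
})
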