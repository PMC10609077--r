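# Shared fixture builders. Everything is generated in code at test time;
# no binary fixtures are stored.

# Smooth aperiodic random field (ice-like texture) for registration tests.
smooth_field <- function(n = 128, seed = 1, sigma = 2) {
  set.seed(seed)
  cryophantom:::fft_gaussian_blur(matrix(rnorm(n * n), n, n), sigma)
}

# Small noiseless grid movie with a fixed-step drift.
fixed_step_movie <- function(dims = c(256, 256), n_frames = 6, total = 8,
                             direction = c(1, 1), grid_step = 64,
                             ice = NULL, dose = FALSE, seed = 3) {
  spec <- phantom_spec(dims, n_frames, grid_step = grid_step, line_width = 5,
                       ice = ice, dose = dose, seed = seed)
  suppressMessages(
    simulate_movie(spec, shift = fixed_step_model(total, n_frames, direction))
  )
}

# Balanced metric table: `p` programs x `n` movies, group means given by
# `means` (recycled), noise sd `sd`.
toy_metric_table <- function(p = 3, n = 10, means = 0, sd = 1, seed = 1) {
  set.seed(seed)
  means <- rep_len(means, p)
  df <- do.call(rbind, lapply(seq_len(p), function(i) {
    data.frame(program = sprintf("prog%02d", i), movie_id = seq_len(n),
               metric = rnorm(n, means[i], sd))
  }))
  as_metric_table(df)
}

# Path to the installed command-line script.
cli_path <- function() {
  system.file("cli", "cryophantom.R", package = "cryophantom")
}

run_cli <- function(args) {
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(system2(rscript, c(cli_path(), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  list(output = out, status = if (is.null(status)) 0L else status)
}
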