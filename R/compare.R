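# Statistical harness for comparing alignment programs: per-metric one-way
# ANOVA across programs, post-hoc pairwise paired t-tests, and pairwise
# Kolmogorov-Smirnov tests on normalized pixel distributions.

#' Read a metric table
#'
#' Loads a CSV of per-(program, movie) quality metrics. The table must have
#' `program` and `movie_id` columns; any remaining numeric columns are
#' metrics (e.g. resolution limit, CV, shift RMSE).
#'
#' @param path CSV file path.
#' @return data.frame of class `metric_table`.
#' @export
read_metric_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_metric_table(df)
}

#' @rdname read_metric_table
#' @param df a data.frame with `program` and `movie_id` columns.
#' @export
as_metric_table <- function(df) {
  for (col in c("program", "movie_id")) {
    if (!col %in% names(df)) stop(sprintf("metric table missing column '%s'", col))
  }
  class(df) <- c("metric_table", "data.frame")
  df
}

.get_metric <- function(table, metric) {
  if (!metric %in% names(table)) {
    stop(sprintf("metric '%s' not found in table", metric))
  }
  data.frame(program = factor(table$program),
             movie_id = table$movie_id,
             value = table[[metric]])
}

#' One-way ANOVA of a metric across programs
#'
#' Tests whether the mean of the chosen metric differs among programs.
#'
#' @param table a `metric_table` (see [as_metric_table()]).
#' @param metric metric column name.
#' @param alpha significance level.
#' @return list with `F`, `p`, `df`, `significant`, `alpha`.
#' @export
anova_across_programs <- function(table, metric, alpha = 0.05) {
  d <- .get_metric(table, metric)
  counts <- table(d$program)
  if (length(counts) < 2) stop("need at least 2 programs")
  if (any(counts < 2)) stop("need at least 2 movies per program")
  wvar <- tapply(d$value, d$program, var)
  if (all(wvar == 0)) {
    stop("degenerate input: zero within-group variance in all groups")
  }
  fit <- aov(value ~ program, data = d)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  list(F = Fv, p = p, df = s[["Df"]],
       significant = p < alpha, alpha = alpha)
}

# Paired t-test robust to the degenerate (near-)zero-variance-difference
# case: identical pairs give p = 1, a constant non-zero difference is
# flagged and treated as significant.
.paired_p <- function(a, b) {
  dif <- a - b
  if (all(dif == 0)) return(list(p = 1, degenerate = TRUE))
  if (sd(dif) <= 1e-10 * max(abs(dif))) {
    return(list(p = 0, degenerate = TRUE))
  }
  tryCatch(list(p = t.test(a, b, paired = TRUE)$p.value, degenerate = FALSE),
           error = function(e) list(p = 0, degenerate = TRUE))
}

#' Post-hoc pairwise paired t-tests
#'
#' Compares every pair of programs by a two-sided paired t-test on the
#' chosen metric, pairing observations by `movie_id` (a balanced design is
#' required). Run after a significant ANOVA, per the usual protocol. Both
#' raw p-values and Bonferroni-adjusted values are reported; the raw
#' decisions correspond to uncorrected post-hoc testing.
#'
#' @param table a `metric_table`.
#' @param metric metric column name.
#' @param alpha significance level.
#' @return data.frame with one row per program pair: `program_a`,
#'   `program_b`, `p`, `p_bonferroni`, `significant`,
#'   `significant_bonferroni`, `degenerate`.
#' @export
posthoc_pairs <- function(table, metric, alpha = 0.05) {
  d <- .get_metric(table, metric)
  progs <- levels(d$program)
  movies <- sort(unique(d$movie_id))
  wide <- matrix(NA_real_, length(movies), length(progs),
                 dimnames = list(movies, progs))
  for (r in seq_len(nrow(d))) {
    wide[as.character(d$movie_id[r]), as.character(d$program[r])] <- d$value[r]
  }
  if (anyNA(wide)) {
    stop("unbalanced pairing: every program needs a value for every movie_id")
  }
  combs <- utils::combn(progs, 2)
  res <- data.frame(program_a = combs[1, ], program_b = combs[2, ],
                    p = NA_real_, degenerate = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(ncol(combs))) {
    pt <- .paired_p(wide[, combs[1, i]], wide[, combs[2, i]])
    res$p[i] <- pt$p
    res$degenerate[i] <- pt$degenerate
  }
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res$significant <- res$p < alpha
  res$significant_bonferroni <- res$p_bonferroni < alpha
  res[, c("program_a", "program_b", "p", "p_bonferroni",
          "significant", "significant_bonferroni", "degenerate")]
}

#' Kolmogorov-Smirnov test on pixel distributions
#'
#' Two-sample KS test comparing the pixel-value distributions of two
#' micrographs. Both images are normalized to mean 0, sd 1 first (so pure
#' scale differences, such as the average-vs-sum output convention, vanish).
#' Because megapixel images make the test arbitrarily powerful, pixels are
#' subsampled (seeded, same index draw for both images when sizes match, so
#' identical inputs give a statistic of exactly 0).
#'
#' @param micrograph_a,micrograph_b numeric matrices.
#' @param n_sample maximum pixels per image (default 1e5); `Inf` disables
#'   subsampling.
#' @param seed subsampling seed.
#' @return list with `statistic` (KS D, in `[0, 1]`) and `p`.
#' @export
ks_pixel_distributions <- function(micrograph_a, micrograph_b,
                                   n_sample = 1e5, seed = 1L) {
  a <- as.vector(micrograph_a)
  b <- as.vector(micrograph_b)
  if (length(a) == 0 || length(b) == 0) stop("empty input")
  if (sd(a) == 0 || sd(b) == 0) stop("degenerate input: constant image")
  a <- (a - mean(a)) / sd(a)
  b <- (b - mean(b)) / sd(b)
  sub <- function(v) {
    if (length(v) <= n_sample) return(v)
    set.seed(seed)
    v[sample.int(length(v), n_sample)]
  }
  a <- sub(a)
  b <- sub(b)
  kt <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(kt$statistic), p = kt$p.value)
}
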