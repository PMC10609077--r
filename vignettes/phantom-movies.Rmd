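---
title: "Phantom movies with known motion: simulation, alignment and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom movies with known motion: simulation, alignment and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryophantom)
```

## Why phantom movies

A cryo-EM movie is a stack of very low-dose frames recorded by a direct
electron detector; the frames drift globally (stage/beam drift) and deform
locally (beam-induced motion, doming of the support film), and they must be
registered before they are averaged into a micrograph. Because the true
motion of real movies is unknown, movie-alignment software is hard to score
objectively. `cryophantom` takes the opposite route: it *generates* movies
whose motion is known exactly, aligns them with a reference
cross-correlation aligner, and scores the result — so any movie-alignment
method can be benchmarked end to end without external data.

## The motion model

Each frame `t = 0 .. T-1` carries a global shift and a radial doming
deformation.

**Parametric drift.** The default drift is

$$x(t) = a_1 t + a_2 t^2 + \tfrac{1}{10}\cos t, \qquad
  y(t) = b_1 t + b_2 t^2 + \tfrac{1}{5}\sin t^2,$$

with defaults $a_1 = -0.039$, $a_2 = 0.002$, $b_1 = -0.02$, $b_2 = 0.002$
(pixels; trigonometric arguments in radians). The linear coefficients set
the drift rate, the quadratic ones its curvature, and the bounded
trigonometric terms add frame-to-frame jitter. Alternatively a
*fixed-step* drift moves the content by `total_shift / (T-1)` pixels per
frame along a fixed direction; this is the controlled stimulus used for
shift sweeps (50–120 px in steps of 10). The sweep direction is a
parameter; the default is the 45° diagonal, and axis-aligned directions are
useful when the per-axis search bound of an aligner is itself under test.

**Doming.** The dome-like bulging of the support is emulated by a
barrel/pincushion transformation acting on per-axis normalized coordinates
(each axis mapped linearly to $[-1, 1]$ about the geometric frame centre,
so corners sit at radius $\sqrt 2$ — this choice keeps the model meaningful
for non-square detectors):

$$r_{out} = r_{in}\,(1 + k_1 r_{in}^2 + k_2 r_{in}^4),$$

with $k_1, k_2$ interpolated linearly from 0.01 (first frame) to 0.015
(last frame), so the deformation grows along the exposure. At these
coefficient scales the mapping is strictly increasing in $r$ (no
fold-over), which the test suite verifies on a grid of radii.

**Rendering convention.** Frames are rendered by *inverse* (output→source)
mapping to avoid scattering artifacts: the source coordinate of output
pixel $p$ is $\mathrm{dome}_k(p) - s_t$. This is exactly the composition
"shift first, then doming", with the doming defined as an output→source
radial resampling, and it fixes the sign convention: a positive shift moves
content toward +x/+y, and the aligner's `cc_shift_pair(a, b)` recovers
$s_b - s_a$ directly. Warping uses bicubic (Catmull-Rom) interpolation with
out-of-frame samples filled by the content mean, so no spurious edges bias
the alignment.

## Frame content

The static content image is built once and deformed per frame — the ice
structure is simulated a single time, as in a real exposure, so frame
differences are purely motion (plus dose noise).

* **Signal.** A regular grid (period 150 px, lines 5 px wide, anchored at
  0-based multiples of the period — the phase is a documented convention),
  a disc pattern (one centred disc or a lattice of discs emulating particle
  projections), or a centred cross. The signal adds `signal_amplitude`
  (default 1) mean electrons on top of the background, keeping Poisson
  means in a realistic range.
* **Ice.** An i.i.d. $N(0,1)$ field, low-pass filtered at
  `pixel_size / lowpass_resolution` cycles/px (default 3 Å at 1 Å/px) and
  rescaled so its minimum and maximum are exactly 0 and 2. The default
  filter is a raised-cosine taper that reaches zero *at* the cutoff, so
  out-of-band power is negligible (≤ 1% of in-band power — an enforced
  contract); a Gaussian filter with half-maximum at the cutoff is available
  for softer spectra, but it leaks substantial power beyond the cutoff and
  is therefore not the default.
* **Dose.** Deterministic frame values are treated as per-pixel Poisson
  means and sampled independently; electron counting makes 0 and 1 the
  most common pixel values at cryo-EM doses. Interpolation overshoot can
  produce slightly negative means; these are clipped to zero and counted.
  Ice and dose use seeds `seed` and `seed + 1`, so a spec reproduces its
  movie bit for bit.

What the phantom does *not* model: contrast transfer function, detector
MTF, realistic macromolecule projections, or non-parametric per-particle
motion. Passing tests on phantoms therefore demonstrate correct recovery of
*parametric* motion under Poisson noise — not performance on any particular
real specimen.

## The reference aligner

The aligner is deliberately a clean, testable member of the same family as
the production tools (cross-correlation plus spline motion models), not a
re-implementation of any of them.

* **Pairwise shifts.** FFT cross-correlation of mean-subtracted frames.
  Correlation maps are Gaussian low-pass filtered (default wavelength
  cutoff 4 px) to suppress shot noise before the peak search, which is
  restricted to ±`max_shift` pixels per axis. The integer peak is refined
  with a 1-D parabola per axis over its 3×3 neighbourhood; ties break
  toward the smaller shift. For a circularly shifted copy the correlation
  surface is exactly symmetric about the peak, so the refinement returns
  the integer shift exactly — a property the tests exploit.
* **Global consensus.** All $\binom{T}{2}$ pairwise measurements enter an
  overdetermined linear system $s_j - s_i = d_{ij}$, solved by
  least squares with the reference frame (default: middle, minimizing
  worst-case extrapolation) fixed at zero. Pairs whose peak lands on the
  search-window boundary are flagged; after each solve, pairs grossly
  inconsistent with the consensus (residual > 2 px) are also flagged and
  the system is re-solved. Periodic content makes the second mechanism
  necessary: a grid with period 150 px aliases a 103 px true shift into a
  confident peak at −47 px, *inside* any 50 px window, where a boundary
  check alone is blind. If more than half of all pairs end up flagged the
  alignment fails loudly — raising `max_shift` (50 → 150) converts that
  failure into an accurate solution for a 120 px drift, reproducing the
  behaviour of production aligners whose expected-shift bound is exceeded.
  The property is demonstrated on a 640×640, 8-frame fixture chosen by
  arithmetic: with an axis-aligned 120 px total drift, 15 of 28 frame
  pairs (54%) exceed a 50 px per-axis bound, while `max_shift = 150`
  respects the peak-search precondition `max_shift < min(dims)/4`.
* **Local motion.** The globally compensated movie is cut into a patch
  grid (`"auto"`: 5×5 below 5000 px width, 7×5 above; patches must be at
  least 128 px). Each patch's per-frame residual shift is measured against
  the patch's *temporal mean* — a deliberate, documented simplification of
  all-pairs per patch — and a cubic B-spline is fitted over $(x, y, t)$
  with `patch_grid + 3` spatial coefficients per axis and $T/2$ temporal
  degrees of freedom. The tensor design is usually rank-deficient, so the
  fit is the minimum-norm least-squares solution via SVD; it reproduces the
  fitted patch shifts to better than 0.1 px.
* **Micrograph synthesis.** Each frame is sampled at $p + s_t$ (plus the
  local field when present) with true cubic B-spline interpolation
  (recursive prefilter, pole $\sqrt 3 - 2$), bilinear interpolation, or a
  Fourier phase ramp (global motion only), then combined as the *average*
  (default) or the *sum* of frames — the two conventions used by published
  tools, differing exactly by the frame count factor. Bilinear
  interpolation measurably damps the top of the spectrum relative to
  B-spline on the same input, mirroring the spectral signature that
  distinguishes production aligners.

## Quality metrics

* **Window triplet.** 512×512 crops from the top-left corner, the centre,
  and the bottom-right corner, plus a normalized (mean 0, sd 1) centre
  window. Doming leaves the centre nearly rigid and curves toward the
  edges, so corner windows blur first.
* **Histogram and CV.** The histogram is taken on raw values before any
  normalization. The coefficient of variation ($100\,\sigma/\mu$) is
  computed after discarding values outside
  $[Q_{10} - 1.5\,\mathrm{IQR}_{80},\; Q_{90} + 1.5\,\mathrm{IQR}_{80}]$,
  where $\mathrm{IQR}_{80} = Q_{90} - Q_{10}$; the 1.5× fence is a
  configurable convention on top of the named 80% interquantile range.
* **Radial PSD.** $|\mathrm{FFT}|^2$ azimuthally averaged with
  integer-rounded radius binning at the resolution of the smaller image
  dimension; profiles are reported to Nyquist and carried on a log scale.
  Full-plane bin totals are preserved so Parseval's identity is checkable.
* **Resolution limit.** The resolution (Å) where the radial PSD first
  drops below 1/100 of its value at the origin, with a Nyquist fallback of
  `2 * pixel_size` when no crossing exists. For raw micrographs the DC bin
  is dominated by the arbitrary intensity offset (it carries the squared
  image sum), so the statistic also accepts `reference = "first"`, using
  the first non-DC bin — that variant is what makes the statistic respond
  smoothly to blur, and it is monotone non-improving under Gaussian blur
  of increasing width.
* **Shift RMSE.** Estimated and true trajectories are re-referenced to the
  estimator's reference frame before the root-mean-square Euclidean error
  is taken, so the overall gauge (which frame defines "zero shift") does
  not count as error.

## Comparing programs

Per-(program, movie) metric tables feed a one-way ANOVA per metric; if it
is significant, post-hoc paired t-tests (paired by movie, two-sided)
compare every program pair. No multiple-testing correction is singled out
by convention here, so both raw and Bonferroni-adjusted decisions are
reported, with the raw column being the protocol-faithful one. Pixel-value
distributions of micrographs are compared with two-sample
Kolmogorov–Smirnov tests after normalizing each image to mean 0, sd 1 —
location and scale differences (such as average-vs-sum output conventions)
vanish by construction, so only genuine shape differences register.
Megapixel images would make the KS test arbitrarily powerful, so pixels
are subsampled (default $10^5$, seeded, with the same index draw for both
images so identical inputs give a statistic of exactly 0). The ANOVA
wrapper's type-I error is calibrated by simulation (1000 null replicates,
3 groups of 10) to the nominal 5% within ±2 points.

## Numerical choices and problem sizes

Degenerate inputs fail loudly rather than silently: zero-variance frames
(flat correlation surfaces), constant centre windows, zero trimmed means,
all-constant ANOVA groups, and malformed MRC headers or sidecars all raise
errors naming the offending quantity. MRC files are written little-endian
(MRC2014, machine-stamped, 1024-byte header, no extended header) and read
in either byte order; mode 6 (uint16) round-trips through R's signed
16-bit writer by wrapping, a documented implementation detail.

The packaged checks run at desk scale, chosen to exercise every code path
while keeping the whole suite fast on a single CPU: 512×512 movies with 10
frames for shift recovery and doming (3×3 patch grids, the smallest grid
with a distinct centre patch at the 128 px patch minimum), 256×256 for
spectral comparisons, and 640×640×8 for the search-bound failure fixture.
Simulations at detector-scale dimensions (4096×4096 and beyond) use the
same code paths and only cost time.

## Worked example

```{r example, eval = FALSE}
spec <- phantom_spec(c(512, 512), n_frames = 10, ice = ice_spec(),
                     dose = TRUE, seed = 1)
mv <- simulate_movie(spec,
                     shift = fixed_step_model(10, 10),
                     doming = deformation_schedule(n_frames = 10))
write_mrc(mv$frames, "movie.mrc")
write_ground_truth(mv$truth, "movie_gt.json")

cfg <- align_config(max_shift = 50, patch_grid = c(3, 3))
ga <- solve_global(mv$frames, cfg)
la <- local_align(mv$frames, ga, cfg)
mic <- render_micrograph(mv$frames, ga, la, cfg)

shift_rmse(ga, mv$truth)                    # pixels
psd_resolution_limit(radial_psd(mic),        # Angstrom
                     reference = "first")
histogram_cv(mic)$cv                         # percent
```

The same pipeline is scriptable from a shell through the thin CLI at
`system.file("cli", "cryophantom.R", package = "cryophantom")` with the
subcommands `simulate` (including `--sweep`), `align`, `evaluate` and
`compare`.

## Known limitations

The local motion measured here is the *doming residual* seen through
patch-sized windows; per-particle Brownian motion is out of scope. The
reference aligner is single-threaded R and is meant as a correctness
baseline, not a throughput competitor. The phantom's grid signal is
periodic, which is exactly what makes aliasing failures reproducible — but
it also means shift bounds should stay below half the grid period unless
the consensus-outlier machinery is the thing under study.
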