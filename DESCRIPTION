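Package: cryophantom
Title: Phantom Cryo-EM Movie Simulation, Reference Alignment and Quality Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates phantom cryo-EM movies with exactly known ground-truth
    motion (parametric drift, barrel/pincushion doming, low-pass filtered
    Gaussian ice, Poisson electron counting), reads and writes MRC2014 image
    stacks with gain/dark correction, provides a reference global and
    patch-based local movie aligner built on FFT cross-correlation with
    sub-pixel peak refinement and cubic B-spline motion interpolation in space
    and time, computes per-micrograph quality metrics (window triplets,
    trimmed coefficient of variation, radially averaged power spectral
    density, PSD-drop resolution limit, shift-recovery error), and supplies a
    statistical harness (ANOVA, paired t-tests, Kolmogorov-Smirnov tests) for
    comparing movie-alignment programs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    splines,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
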