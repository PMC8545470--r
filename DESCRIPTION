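Package: nacremeso
Title: Mesoscale Order and Growth Statistics of Nacre
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies mesoscale periodicity in nacre (mother-of-pearl) from
    cross-sectional micrographs and tablet-thickness profiles. Detects
    interlamellar sheaths as intensity minima along transects perpendicular to
    the layering, builds tablet-thickness profiles and maps, computes the 1D
    pair-correlation function with per-order Gaussian peak fits and a
    paracrystal broadening assessment, estimates the corrective-growth
    (adjacent-tablet) correlation, fits the 1/f^alpha spectral exponent of
    thickness fluctuations, measures angular interface order from the 2D
    Fourier transform, and computes topological-defect densities. Includes a
    synthetic nacre generator with per-interface ground truth for validating
    every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    tiff,
    png,
    Matrix,
    EBImage
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
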