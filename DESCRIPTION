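Package: nucsaxs
Title: Contrast-Variation SAXS Analysis of Nucleosome Disassembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing salt-induced nucleosome core particle
    disassembly with (time-resolved) small-angle X-ray scattering under
    sucrose contrast variation. Builds coarse-grained bead models of
    nucleosomal DNA in wrapped, partially released and free states, computes
    theoretical scattering by the Debye formula under a three-phase contrast
    model, inverts profiles to pair-distance distributions P(R) with a
    regularized indirect Fourier transform and a Dmax selection scan,
    classifies the diagnostic d1/d2/d3 length scales, fits measured profiles
    with non-negative ensembles of pool conformers, and analyses stopped-flow
    time series by singular value decomposition and exponential rate fitting.
    A synthetic-data generator with recorded ground truth drives testing and
    worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    pracma,
    minpack.lm,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
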