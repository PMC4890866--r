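Package: protsca
Title: Statistical Coupling Analysis of Protein Sequence Alignments
Version: 0.1.0
Authors@R:
    person("protsca", "developers", email = "protsca@example.org",
           role = c("aut", "cre"))
Description: Statistical coupling analysis (SCA) of protein multiple
    sequence alignments: alignment preprocessing (gap filtering, sequence
    weighting against phylogenetic redundancy, weighted resampling),
    position-specific conservation by Kullback-Leibler relative entropy,
    a conservation-weighted covariance matrix of amino-acid coevolution
    with Frobenius- or spectral-norm compression, eigendecomposition
    against a column-scrambling randomization null, rotation of the
    significant eigenmodes by independent component analysis, mapping of
    positional modes into sequence space through a reduced alignment, and
    heuristic grouping of independent components into protein sectors.
    Includes a planted-sector synthetic alignment generator for
    validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
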