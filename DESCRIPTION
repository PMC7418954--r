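Package: laryngevol
Title: Phylogenetic Comparative Analysis of Larynx-Size Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landmark-based laryngeal morphometrics and phylogenetic
    comparative analysis of larynx-size evolution across mammalian clades.
    Builds a principal-component "larynx size" axis from interlandmark
    distances, fits phylogenetic generalized least squares regressions with
    Pagel's lambda, tests allometric grade shifts by phylogenetic ANCOVA and
    multi-regime Ornstein-Uhlenbeck shift detection with parametric-bootstrap
    support, compares clade-wise Brownian-motion evolutionary rates by
    permutation, reconstructs ancestral states for phenograms, and relates
    larynx size to call fundamental frequency and social group size. Includes
    a fully parameterized synthetic-data generator (trees, traits, landmarks,
    acoustics) so the entire pipeline is testable without access to the
    original specimen data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
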