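Package: stochtopo
Title: Topological Analysis of Non-Equilibrium Markov State Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Build continuous-time Markov state networks composed of
    translationally invariant bulk regions joined at interfaces, tilt their
    master-equation generators by a current-counting field, and classify the
    bulks by winding numbers of the Bloch-determinant phase. The winding
    mismatch across an interface predicts topologically protected localized
    steady states, which the package verifies through an interface index,
    determinant-root localization lengths, the protected window of the tilt
    field, and kinetic Monte Carlo simulation. Includes model builders for
    two-bulk ladder lattices, a chemosensory adaptation lattice, and kinetic
    proofreading chains, with quenched rate disorder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
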