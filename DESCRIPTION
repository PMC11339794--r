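Package: hindamine
Title: Steric Descriptors and Best-Subset Screening for Hindered Amines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the steric environment of trisubstituted nitrogen
    centres and relates it to thermodynamic and kinetic response data.
    Implements the percent buried volume (%V_Bur) descriptor on a voxel grid
    with quadrant decomposition and topographic steric maps, a Monte-Carlo
    cross-check, nitrogen pyramidalization indices, auxiliary geometric
    descriptors (longest C-N bond, van der Waals molecular surface area),
    descriptor-table assembly from XYZ geometries plus externally computed
    quantum-chemical columns, and an exhaustive 1-3 variable multilinear
    (best-subset) regression screen with subgroup filters and robustness
    variants. Includes generators for synthetic amine geometries of tunable
    bulk and pyramidality and for descriptor tables with planted linear
    models, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
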