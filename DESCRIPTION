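Package: mgeflux
Title: Metabolic Burden of Mobile Genetic Elements in Genome-Scale Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based analysis of the metabolic cost that mobile
    genetic elements (conjugative plasmids, filamentous phage) impose on
    their bacterial hosts. Builds biomass pseudoreactions for a mobile
    element from its genome and proteome composition (stoichiometric
    coefficients in mmol per gram of element), integrates them into a host
    genome-scale metabolic model, and quantifies host-element conflict via
    flux variability analysis range overlap, parsimonious-FBA subsystem
    demand fold-changes, and dynamic FBA simulations of batch mono- and
    co-cultures of cross-feeding communities. Includes an exact two-phase
    simplex solver for the underlying linear programs, a brute-force
    flux-polytope vertex enumerator used as a test oracle, and generators
    for small analytically tractable fixture models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
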