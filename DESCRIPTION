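Package: colonet
Title: Dispersal Simulation and Provable Minimum Colonisation Times on
    Dendritic Habitat Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for graph-based dispersal modelling of aquatic
    invertebrates with a terrestrial life stage. Generates artificial
    landscapes (a random-cluster neutral landscape model plus a synthetic
    dendritic stream network), builds least-cost-path habitat networks on
    a land-cover cost raster, runs a deterministic discrete-time dispersal
    simulation with cost-dependent biomass allocation and mortality, and
    solves a quickest-flow mixed integer program on a time-expanded copy
    of the habitat network that returns a provable lower bound on the
    number of time steps needed to colonise designated destination
    habitats. Includes the paired simulation/optimisation experiment
    design and its comparison statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: Python (>= 3.8) with scipy (>= 1.9) on the PATH
    (HiGHS backend for the mixed integer program)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
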