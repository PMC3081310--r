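Package: dirpol
Title: Individual-Based Simulation of Nucleotide Polymerase Directionality Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based evolutionary simulator for populations of simple
    replicators whose polymerases synthesize nucleic acid either in the
    forward (5'->3') or reverse (3'->5') direction.  Organisms replicate a
    genome at a heritable integer rate, suffer spontaneous nucleotide
    triphosphate hydrolysis with a Boltzmann-factor probability that
    penalizes the reverse strategy, misincorporate nucleotides at a rate
    coupled to polymerase speed, and compete in a capacity-limited
    environment with density-dependent random culling.  The package ships
    the isolation and competition experiment designs as seeded presets,
    ensemble averaging over replicate runs, log-linear regression of the
    reverse-subpopulation decline against simulation temperature, and a
    command-line interface that writes tidy tab-delimited time series.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
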