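Package: idpblob
Title: Blob Decomposition and Tertiary Contact Enrichment for Disordered Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical hydropathy-based decomposition of intrinsically
    disordered protein sequences into blobs, groups and regions, with
    Das-Pappu charge-patterning metrics (kappa, NCPR, FCR) and Uversky
    classification; blob-level excess-distance contact maps from
    conformational ensembles; a freely-jointed self-avoiding heteropolymer
    (SAHP) Monte Carlo null model for detecting enrichment of tertiary
    contacts; Ramachandran-region secondary-structure propensities and
    run-length maps; cluster tests for coupling between inter-blob contacts
    and beta-strand formation; secondary chemical-shift arithmetic and
    Stokes-Einstein hydrodynamic radii; and a synthetic-ensemble generator
    with planted contact probabilities and planted contact-beta coupling
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    seqinr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
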