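Package: nanogmicelle
Title: Coarse-Grained Slab Simulations and Condensate Analysis of Nanog
    Micelle-Like Clusters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Residue-level coarse-grained model of the human Nanog
    transcription factor and DNA, with hydrophobicity-scale (Ashbaugh-Hatch)
    nonbonded interactions, Debye-Hueckel electrostatics, excluded volume and
    an elastic-network treatment of the folded DNA-binding domain. Provides a
    Langevin dynamics engine for periodic slab boxes (shrink-to-condensate and
    random-start protocols), the condensate analyses used to characterise
    micelle-like clusters (interaction-graph and tryptophan-repeat contact
    clustering, z-density profiles, dilute-phase concentration, domain radial
    profiles, mean-square displacement and diffusion, FRAP-like tracking,
    DNA-DNA distance statistics), and synthetic fixture generators with
    planted structure so that every analysis is testable without running
    molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
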