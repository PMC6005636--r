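Package: dimerscope
Title: Ensemble Analysis of Membrane-Protein Dimerization
Version: 0.1.0
Authors@R:
    person("Dimerscope", "Developers", email = "dimerscope@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize how two membrane-transporter protomers
    associate into dimers in a lipid bilayer. Provides a seeded rigid-body
    Brownian-dynamics generator of docking-assay style ensembles (many
    independent replicates of two randomly oriented protomers), relative
    orientation (beta/chi) coordinates and toroidal density clustering,
    residue-residue interface contact maps with a bundle-domain exclusion
    screen, umbrella-sampling window planning and WHAM free-energy profiles
    with block-bootstrap errors, lipid order-parameter and bilayer thickness
    maps, and ensemble convergence diagnostics, together with text-based
    GRO/PDB/CSV readers and writers and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
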