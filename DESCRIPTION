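Package: brushmc
Title: Grand-Canonical Monte Carlo of Polymer Brushes Under AFM Compression
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grained simulation of the mechanical response of polymer
    brushes grafted on soft surfaces, as probed by an atomic force microscope.
    Implements a grand-canonical Metropolis Monte Carlo sampler for
    bead-spring chains with soft (DPD-type) repulsive interactions and
    explicit monomeric solvent confined between a deformable grafting surface
    and a repulsive tip wall; builders for uniform ("normal cell") and
    three-population ("cancerous cell") brush architectures in their liquid
    (laterally mobile grafts) and solid (immobile grafts) variants; tip-force,
    density-profile, brush-height and graft-meandering observables; and an
    Alexander-de Gennes theory layer with Derjaguin sphere forces and
    multi-population force-curve fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
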