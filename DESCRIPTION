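Package: neuropilMorph
Title: Serial-Section EM Morphometry of Presynaptic Boutons, Mitochondria
    and Synapses
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for three-dimensional morphometry of cortical neuropil
    reconstructed from serial-section electron microscopy. Converts
    integer-label volumes of presynaptic boutons, their mitochondria and
    synaptic appositions into per-object surface areas and volumes via
    watertight iso-surface meshes, estimates synapse contact areas from
    per-section apposition lengths, applies an unbiased counting-frame
    sampling scheme on a reference section, classifies mitochondria as
    straight, curved or toroidal from skeleton bend angles and surface
    topology, and tests the ultrastructural size principle with Pearson
    correlations, Model II (reduced major axis) regressions, Fisher
    r-to-z comparisons and ANOVA/Tukey batteries. Includes a seeded
    synthetic-neuropil generator that emulates young-adult and aged
    (cognitively unimpaired/impaired) regimes with known ground truth, so
    every pipeline stage is verifiable without raw EM data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: ElectronMicroscopy, Preprocessing, StatisticalMethod, Software
RoxygenNote: 7.3.3
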