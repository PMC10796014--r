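Package: chitosim
Title: Subsite-Preference Simulation and Mass-Spectrometric Analytics for
    Chitosan Acetylation Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how chitin deacetylases (CDAs) shape the
    pattern of acetylation (PA) of chitosans and chitooligosaccharides.
    Provides exact monoisotopic mass computation for partially acetylated
    chitooligosaccharide (paCOS) species, a stochastic Boltzmann model of
    CDA binding frames with per-subsite GlcNAc/GlcN preference energies
    driving deacetylation and N-acetylation trajectories, in silico
    chitinosanase fingerprinting with weight-average A- and D-block
    statistics, MS1 species quantification and relative-acetate-release
    statistics, B/Y fragment-ion pattern deconvolution of MS2 spectra,
    site-saturation-mutagenesis plate-screen analytics (glucosamine
    standard regression, control normalization, SD-threshold outlier
    elimination), and seeded synthetic-data generators so every stage is
    testable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
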