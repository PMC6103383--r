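Package: dectk
Title: Dual-Energy Micro-CT Spectral Shaping, Co-Registration and
    Three-Material Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for dual-energy microcomputed tomography
    (DECT) on gantry-based preclinical scanners. Models polychromatic
    tungsten-anode x-ray spectra and beam filtration from packaged
    mass-attenuation tables, solves filter-design problems (thickness for a
    target flux reduction, foil-equivalent nanoparticle mass loading for
    resin-cast annular filters, half-value-layer analysis), co-registers
    sequential low- and high-energy image volumes from embedded fiducial
    markers by closed-form least-squares rigid fitting, and decomposes
    co-registered volume pairs into soft-tissue, bone and contrast-vessel
    volume-fraction maps from six pure-material calibration values. A
    synthetic dual-energy phantom generator with ground truth, beads, noise
    and known misalignment makes the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
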