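Package: txmkit
Title: Data Evaluation for Full-Field Transmission X-Ray Microscopy
Version: 0.1.0
Authors@R: person("TXM", "Tools", email = "txmkit@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for full-field transmission X-ray microscopy
    (TXM) data evaluation: reading and flat-field correcting image stacks,
    zone-plate optics and energy-dependent magnification correction,
    phase-correlation image registration, dual-energy (2E) elemental difference
    mapping, mosaic stitching with motor-position seeding and feathered
    blending, parallel-beam tomographic reconstruction (filtered back
    projection and iterative ART), and per-pixel XANES spectro-imaging with
    edge-jump/edge-energy mapping, linear-combination fitting, R-factor maps
    and RGB phase maps.  Synthetic phantom generators provide ground-truth
    test surfaces for every pipeline stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    rhdf5,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
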