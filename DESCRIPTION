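Package: helmetplan
Title: SAR-Based Design of UWB Helmet Applicators for Deep Microwave Hyperthermia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing ultra-wide-band (250-500 MHz) helmet antenna
    applicators for deep microwave hyperthermia of brain tumors. Provides layered
    voxel head phantoms with per-tissue dielectric and thermal property tables, an
    analytic single-antenna field oracle, fast approximation of the E-field of an
    antenna at an arbitrary scalp location by barycentric interpolation over a
    repulsion-spread surface grid, array mutual-coupling correction fitted from
    pair experiments, multi-frequency SAR assembly with 5 g mass averaging and
    hot-to-cold-spot-quotient (HCQ) treatment-plan optimization, global antenna
    arrangement optimization by constrained random search with sorted local
    refinement, and a steady-state Pennes bioheat solver with power scaling to a
    healthy-tissue temperature limit and T50/T90 target indexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
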