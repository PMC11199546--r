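Package: fetalox
Title: Fetal Cardiovascular MRI Flow, Oximetry and Oxygen-Transport Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative pipeline from fetal cardiovascular MRI raw signals to
    whole-circulation oxygen-transport physiology. Provides cine phase-contrast
    flow quantification (phase-to-velocity mapping, background-offset and
    aliasing correction, ROI flow integration), blood T2-relaxometry oximetry
    (mono-exponential T2 fitting over a central-fraction vessel ROI and a
    Luz-Meiboom-type T2 to oxygen-saturation calibration), assembly of measured
    vessel flows into the fetal-circulation shunt model (pulmonary blood flow,
    ventricular outputs, foramen ovale and lower-trunk flows, flow distribution
    as a fraction of combined ventricular output), Fick-principle oxygen
    delivery, consumption and extraction, MRI volumetry-based fetal and brain
    weights, and the mixed (split-plot) two-way repeated-measures ANOVA used to
    compare growth-restricted and control fetuses across normoxic and acutely
    hypoxic states. Includes seeded generators for phase-contrast and
    T2-prepared image phantoms, label-map volumes and virtual cohorts so that
    every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
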