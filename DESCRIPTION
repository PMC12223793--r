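Package: aoctel
Title: Airway Compliance Elastography from Anatomical OCT and Intraluminal Pressure
Version: 0.1.0
Authors@R: person("aoctel", "developers", email = "aoctel@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of anatomical optical coherence tomography
    (aOCT) elastography of the airway: a synthetic simulator of a thick-walled
    elastic tube ventilated under pressure control and rendered into polar
    aOCT frame stacks; segmentation of the air-tissue interface with fold-over
    (aliasing) correction and sheath-based pixel-scale calibration; per-frame
    pressure synchronization, respiratory-cycle extrema extraction, and
    computation of cross-sectional compliance (CC) and normalized
    cross-sectional compliance (nCsC) with uncertainties; and study-level
    multiway ANOVA and linear regression of nCsC and histologic injury grade
    on steam intensity, time, and airway position.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
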