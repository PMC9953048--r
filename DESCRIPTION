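Package: facemetrics
Title: Landmark-Based Quantification of Mouse Facial Expressions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rodent facial expressions from profile
    landmarks. Implements a seven-parameter geometric scheme (eye opening,
    ear opening, ear angle, ear position, snout position, mouth position,
    face inclination) built exclusively from ratios and angles so that the
    measures are invariant to camera zoom, translation and rotation.
    Includes frame selection and per-individual aggregation into stimulus
    units, baseline-normalized response profiling with one-sample tests,
    the associated ANOVA/post-hoc battery (Tukey, Dunnett, Sidak,
    Greenhouse-Geisser correction), inter-observer reliability via the
    intraclass correlation coefficient, principal component analysis with
    variable contributions and Horn's parallel analysis, UMAP embedding of
    stimulus units, and a synthetic-face simulator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    car,
    emmeans,
    mvtnorm,
    uwot,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    cluster,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
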