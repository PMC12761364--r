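Package: miaqsar
Title: Image-Based QSAR Modelling, Validation and Candidate Design for
    Congeneric Inhibitor Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate image analysis QSAR (MIA-QSAR) for congeneric
    small-molecule series: rasterises aligned 2D structure sketches into
    property-weighted pixel descriptors (electronegativity, van der Waals
    radius and their ratio), fits centred NIPALS partial least squares
    models, and runs the full chemometric validation battery
    (leave-one-out q2, Y-randomization with c-r2p, bootstrap external
    validation with Roy's r2m metrics and Lin's concordance correlation,
    Williams-plot outlier analysis). Includes interpretation maps (VIP and
    coefficient plots), substituent-based candidate enumeration and
    ranking against a reference inhibitor, docking-evaluation arithmetic
    (pose RMSD, Docking Accuracy, binding-energy decomposition totals,
    activity-energy regression with lack-of-fit analysis), and a synthetic
    congeneric-series generator with planted structure-activity effects
    for end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
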