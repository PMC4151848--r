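Package: aortamech
Title: Tensile Rheology and Histomorphometry of the Developing Aortic Wall
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for uniaxial tensile tests and stained-section
    histomorphometry of arterial wall strips. Converts raw force-displacement
    traces and strip geometry into stress-strain curves, incremental elastic
    moduli, stress-relaxation strength, plastic deformation and wall geometry;
    quantifies smooth-muscle, elastin and collagen area fractions from
    Elastica-van Gieson stained fields and counts nuclei in hematoxylin-eosin
    fields; compares study groups with one-way ANOVA and Scheffe post-hoc
    tests. A quasi-linear viscoelastic protocol simulator and a synthetic
    stained-section renderer provide ground-truth data so every stage can be
    exercised without instrument output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
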