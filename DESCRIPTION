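Package: equimorph
Title: Geometric Morphometrics of the Equine Dorsal Profile and Welfare Indicators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics of the horse's dorsal
    outline (croup to head) and its statistical linkage to rule-scored welfare
    indicators. Reads and writes tpsDig-style TPS landmark files, performs
    Generalized Procrustes Analysis, thin-plate-spline bending energy and
    sliding semilandmarks, articulation-angle stabilization around the
    withers, shape PCA with deformation grids, rule-based scoring of
    stereotypic/abnormal repetitive behaviour, depressed-like posture and ear
    position, and mixed-model ANOVA of principal-component scores with the
    individual as a random factor. Includes a synthetic dorsal-profile
    generator so the whole pipeline can be exercised and validated without
    photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
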