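Package: refugia
Title: Palaeoclimatic Habitat Hindcasting and Provenance-Trial Variance
    Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to reconstruct the post-glacial biogeography of a tree
    species from climate and common-garden data.  Derives biologically
    relevant bioclimatic variables (growing and chilling degree-days,
    continentality, seasonal precipitation sums, frost-free days,
    precipitation as snow) from monthly climate normals; applies
    coarse-resolution palaeoclimate anomalies to a fine baseline by the
    delta method; fits an ensemble-classifier species distribution model
    and hindcasts probability-of-presence surfaces for late-Pleistocene and
    Holocene periods; validates hindcasts against fossil-type presence
    records by the area under the ROC curve; maps glacial-refugium habitat
    stability as the product of present-day and Last Glacial Maximum
    presence probabilities; and estimates regional within-population
    variance components from randomised complete block provenance trials by
    REML, with standard errors from the information matrix.  A synthetic
    data module generates every input with known ground truth so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
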