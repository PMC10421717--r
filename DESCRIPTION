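Package: fluctasym
Title: Fluctuating Asymmetry Analysis of 3D Landmark Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric quantification of fluctuating asymmetry
    (FA) in structures with object symmetry, such as primate crania. Reads
    3D Slicer fiducial markup (.fcsv) and TPS landmark files, performs
    generalized Procrustes superimposition of original and reflected-relabeled
    configurations, decomposes shape into symmetric and asymmetric components,
    runs a replicate-based Procrustes ANOVA separating directional asymmetry,
    FA and digitizing error, extracts per-individual Procrustes FA scores,
    and models FA against demographic and environmental-exposure covariates
    with linear mixed-effect models, Tukey post hoc contrasts under Holm
    correction, and simulation-based power analysis. Includes a synthetic
    landmark-data generator with controllable symmetric variation,
    directional asymmetry, individual FA and measurement error.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    lmerTest,
    multcomp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
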