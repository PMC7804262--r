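Package: enameldepth
Title: Quantify Enamel Defect and Perikymata Depths from Confocal Profilometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for linear enamel hypoplasia (LEH) and
    perikymata depths on high-resolution tooth-surface topographies. Reads XYZ
    point clouds exported by confocal profilometers, interpolates digital
    elevation models over a Delaunay triangulation, extracts transect profiles,
    detects ridges and grooves with an amplitude-threshold peak pruner, and
    measures defect and growth-increment depths from the occlusal shoulder.
    Includes plane and sphere form-removal leveling with bias reporting, LEH
    severity ratios with a species/tooth-type fallback reference, Table-style
    group summaries, Pearson correlation and linear mixed models with specimen
    random intercepts, and a seeded synthetic tooth-surface simulator with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    emmeans,
    interp,
    jsonlite,
    lme4,
    lmerTest,
    readr,
    stats,
    tibble,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
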