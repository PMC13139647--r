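Package: canopyfill
Title: Canopy Space Filling and Stand Productivity from Voxelised Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline relating canopy space filling to stand
    productivity in planted tree-diversity experiments. Voxelises plot-level
    3D point clouds into regular cubic grids, detects canopy boundary heights
    (canopy top, lowest green branch, 10 percent occupancy height), computes a
    canopy space filling index (CSFI) under four vertical canopy-space
    definitions (total, top, mid, main), derives subplot-level annual wood
    productivity (AWP) from two-census tree inventories, and quantifies the
    CSFI-AWP relationship with gamma log-link mixed models including marginal
    R-squared. A synthetic stand generator emulating a 45 x 45 m
    monoculture/mixture planting design produces point clouds, inventories and
    model-generated AWP with known ground truth, so the full chain is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
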