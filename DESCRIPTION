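Package: mechimg
Title: Finite-Element Simulation of Mechanical Imaging of the Compressed Breast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of mechanical imaging (MI) acquisition during
    mammographic compression. Generates procedural half-ellipsoid breast
    phantoms with embedded stiff spherical lesions, meshes them with a
    structured tetrahedral decomposition, solves quasi-static plate
    compression with a linear-elastic finite-element model and frictionless
    rigid-plate contact, extracts the surface pressure on a 1 x 1 cm sensor
    grid, and computes the relative mean pressure over lesion area (RMPA)
    statistic together with sweep-level stress summaries and exact Wilcoxon
    signed-rank comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    tibble,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    png,
    optparse
Config/testthat/edition: 3
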