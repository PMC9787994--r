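Package: forestbirdiv
Title: Forest Structure and Breeding Bird Diversity from Airborne LiDAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links LiDAR-derived forest structure to taxonomic and functional
    bird diversity in managed plantation forests. Provides canopy height model
    handling and six stand-level structural metrics (top canopy height, gap
    fraction, Moran's I horizontal heterogeneity, vertical evenness of the
    MacArthur-Horn plant-area profile, shrub density and canopy density) at
    multiple raster resolutions; detectability-corrected community assembly of
    two-visit breeding bird surveys over management/age-class compartment
    groups; species richness, Shannon diversity and convex-hull based
    functional diversity metrics (FRic, FEve, FDiv, FDis) with Box-Cox
    normalisation; hierarchical partitioning of regression R-squared for
    variable importance and spatial-resolution optimisation; and final linear
    models with type-2 ANOVA. A seeded synthetic landscape, LiDAR and bird
    survey generator with known ground truth makes the full pipeline testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    MASS,
    vegan,
    lmtest,
    sp,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    cluster
Config/testthat/edition: 3
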