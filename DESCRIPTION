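Package: seedfda
Title: Functional Data Analysis of Seed Germination and Physical Dormancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models daily cumulative germination (imbibition) counts as smooth
    absolute germination distribution functions using penalized B-spline
    regression, classifies accessions into dormancy categories by UPGMA
    clustering of spline descriptors, and relates germination pattern to the
    environment of origin with spatially explicit statistics: Moran's I
    correlograms, Dutilleul's modified t-test, PCNM spatial eigenvectors,
    redundancy analysis with forward selection and pure/shared variance
    partitioning, and niche-overlap equivalency tests on gridded suitability
    surfaces. Includes seed-coat trait statistics (Kruskal-Wallis,
    proportional-odds ordinal regression, ANCOVA with custom contrasts) and a
    synthetic-study generator reproducing the statistical structure the
    analysis assumes: latent dormancy classes, spatially autocorrelated
    environmental fields with a class-linked variable, and class-structured
    trait distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS,
    vegan,
    geosphere,
    pracma,
    car,
    emmeans,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
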