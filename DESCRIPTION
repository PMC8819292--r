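Package: foveatopo
Title: Foveal Cone and RPE Cell Topography and Foveal Shape Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voronoi-based analysis of foveal cone photoreceptor and retinal
    pigment epithelium (RPE) cell mosaics along the horizontal meridian:
    per-cell inter-cell distances (ICD), region-of-interest densities under a
    hexagonal-packing assumption, and cones-per-RPE-cell counting; asymmetric
    power-law and generalized-exponential nonlinear mixed-effects models of
    log10 cell density versus eccentricity with AIC-based family selection and
    likelihood-ratio tests; a linear mixed-effects model of retinal thickness
    on log10 cone and RPE ICDs with a between-individual variance
    decomposition; method-agreement statistics (Deming regression via the
    first principal component, Bland-Altman limits of agreement, one-way
    intraclass correlation, Pearson and partial correlations); and seeded
    synthetic-study generators (quasi-hexagonal mosaics, thickness profiles,
    rater replicates) for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    FNN,
    nlme,
    lme4,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
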