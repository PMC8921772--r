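Package: floralsel
Title: Pollinator-Mediated Phenotypic Selection on Floral Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates standardized directional and quadratic (stabilizing or
    disruptive) selection gradients on floral traits from plant-level field
    data, forms the pollinator-mediated selection contrast between open- and
    supplementally hand-pollinated plants with propagated standard errors,
    quantifies pollen limitation with bootstrap confidence intervals, and
    tests for variation in selection across sites, years and nutrient
    treatments with factorial ANOVA and ANCOVA interaction models. Includes a
    synthetic-data generator that emulates two field experimental designs
    (two sites by two years, and a nutrient-addition common garden) with
    correlated floral traits, treatment-dependent seed set and injectable
    true selection surfaces, so the whole pipeline can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    boot,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
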