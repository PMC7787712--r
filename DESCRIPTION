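Package: crabtherm
Title: Behavioral Thermoregulation Analysis for Burrowing Intertidal Ectotherms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates behavioral thermoregulation parameters of burrowing
    intertidal ectotherms (fiddler crabs) from field records of body, surface,
    and burrow temperatures: the burrow use efficiency (slope of
    thermoregulation capacity Tb - S on cooling capacity B - S), the operative
    no-refuge offset (intercept of that line), and the onset body temperature
    at which animals begin using burrows to thermoregulate. Includes
    from-first-principles ordinary least squares and sequential ANCOVA,
    re-implementations of the Kruskal-Wallis H test with Dunn's post hoc
    comparisons and of distance-matrix permutational ANOVA (pseudo-F with
    permutation p-values), a synthetic field-data generator with a piecewise
    behavioral model, and a pipeline that ties validation, classification,
    fitting, and reporting together.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
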