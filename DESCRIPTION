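Package: synovasim
Title: Delayed Kinetic Model of Post-Injury Synovial Inflammation Under
    Sex-Hormone Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates the acute inflammatory cascade in the knee synovium
    after anterior cruciate ligament injury as a delayed ordinary
    differential equation network of platelets, M1/M2 macrophages,
    synovial fibroblasts and eight soluble mediators (IL-1beta, TNF-alpha,
    IL-6, IL-10, TGF-beta, TIMP-1, MMP-9, MMP-1).  Constant estrogen,
    progesterone and testosterone concentrations modulate mediator
    production through saturating and exponential feedback functions.
    Includes pre-injury steady-state initialisation from the
    fibroblast-only subsystem, Latin hypercube sampling of production and
    decay coefficients for uncertainty bands, hormone-condition ensembles
    for male and female physiological ranges, and per-day nonparametric
    comparison of conditions (Kruskal-Wallis with Mann-Whitney U post hoc
    tests and Bonferroni correction).  A synthetic parameter generator
    provides complete, unit-consistent coefficient sets for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
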