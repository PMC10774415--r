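Package: medflydrive
Title: Stochastic Simulation of Homing Gene Drives and Genetic Sex
    Conversion in the Mediterranean Fruit Fly
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Agent-based, discrete-generation simulation of CRISPR-Cas9
    homing gene drives for population suppression of the Mediterranean
    fruit fly (Ceratitis capitata), built on medfly sex-determination
    genetics: zygotic transformer (tra) function, maternal tra provision,
    and the Y-linked male determiner. Four suppression architectures are
    modelled (female-fertility homing, tra homing, sterilising sex
    conversion, and dual fertility targeting), with germline cleavage,
    homology-directed repair, functional (R1) and non-functional (R2)
    resistance allele formation, and maternal Cas9 deposition. Includes
    exact analytic gamete distributions as an oracle for the stochastic
    germline model, parameter sweeps with local polynomial smoothing of
    extinction surfaces, a synthetic cross-progeny generator, and
    statistics for cross count tables (super-Mendelian transmission rates,
    chi-square goodness of fit, and inference of cleavage and HDR rates
    from marker and phenotype fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
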