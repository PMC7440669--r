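Package: cobaflux
Title: Co-Factor Balance Assessment for Constraint-Based Metabolic Models
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constraint-based modelling toolkit for assessing the ATP and
    NAD(P)H balance of engineered production pathways in the Escherichia coli
    core metabolic network. Builds a catalogue of butanol and butanol-precursor
    producer models on top of the bundled reduced core model, optimises them
    with flux balance analysis (FBA), parsimonious FBA, flux variability
    analysis and minimisation of metabolic adjustment (MOMA), partitions
    co-factor fluxes into production, biomass, target, waste and maintenance
    categories, iteratively caps futile co-factor cycles against a wild-type
    reference, evaluates the analytic Dugar-Stephanopoulos pathway-yield
    chain, applies flux ranges derived from 13C flux datasets, and sweeps
    co-factor stoichiometry landscapes on the terminal reductase step.
    Linear programs are delegated to the GLPK command-line solver; quadratic
    programs use the Goldfarb-Idnani solver from 'quadprog'.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    quadprog,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: GLPK command line solver (glpsol)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
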