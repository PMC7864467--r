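Package: petabkit
Title: Parameter Estimation Problems for Systems Biology in the PEtab Format
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Read, write, validate and evaluate parameter estimation problems
    for dynamical models in systems biology specified in the PEtab v1 tabular
    format. A PEtab problem couples an SBML reaction model with tab-separated
    tables of experimental conditions, measurements, observables, parameters
    and optional visualization specifications, grouped by a YAML file.
    The package resolves the hierarchical parameter-override rules into
    per-condition mappings, evaluates observation and noise models (normal and
    Laplace, on linear, log and log10 scales), computes chi-square and negative
    log-likelihood objectives, simulates a restricted SBML subset with
    steady-state pre-equilibration and partial state reinitialization,
    packages problems into COMBINE archives, renders time-course and
    dose-response figures, and generates a suite of toy test problems with
    analytic reference values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
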