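Package: phytocycle
Title: Plant Cell-Cycle Network Simulation and Cell-Size Homeostasis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a parsimonious ordinary-differential-equation model of
    the plant cell-cycle protein network (CDKA:CYCD, KRP, E2FA/B, RBR, FBL17,
    CDKA/B:CYCB, MYB3R3/4, SMR, SCF, APC) with a quasi-steady-state layer for
    fast binding and phosphorylation reactions. The network is embedded in
    exponentially growing cells with event detection for the G1/S and G2/M
    transitions, and iterated over stochastically dividing lineages to study
    cell-size homeostasis under competing hypotheses: size-independent
    inhibitor synthesis, equal inheritance of chromatin-bound inhibitors, and
    phase-dependent inhibitor expression.  Includes reference sizer, adder and
    timer population models, bifurcation analysis of the isolated checkpoint
    switches, limit-cycle detection and parameter robustness scans, dispersion
    and best-fit-slope statistics, and simulated over/under-expression
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
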