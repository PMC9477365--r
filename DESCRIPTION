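Package: fibrintrap
Title: Thrombin-Fibrin Bivalent Binding and Fibrin Polymerization Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled models of thrombin-fibrin interaction during fibrin
    polymerization. A single-molecule stochastic simulator (Gillespie direct
    method with an exact absorbing-Markov-chain oracle) estimates thrombin
    residence times at fibrin monomer-monomer junctions with and without
    bivalent gamma-prime binding. A mass-action ordinary differential
    equation model couples thrombin-mediated fibrinopeptide A/B cleavage,
    oligomer/protofibril/fiber polymerization, steric inhibition by
    gamma-prime chains, and thrombin binding to polymerized fibrin.
    Fiber-structure metrics (protofibril number, clot time, circle-packing
    inaccessible fraction) yield estimates of thrombin trapped inside fibrin
    fibers, and a multistart constrained least-squares workflow fits the
    polymerization parameters to clot-time-ratio data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
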