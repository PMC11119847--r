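Package: quboDock
Title: Fragment-Based Protein-Ligand Flexible Docking as a QUBO Problem
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Formulates fragment-based protein-ligand flexible docking as a
    quadratic unconstrained binary optimization (QUBO) problem. A compound is
    decomposed into rigid, hydrogen-capped fragments; candidate fragment
    placements carrying binding-free-energy scores become binary variables;
    a four-term Hamiltonian (placement fitness, steric clash penalty,
    covalent-bond reward, one-placement-per-fragment constraint) is assembled
    as an explicit QUBO; solutions are found by exhaustive enumeration or
    multi-restart simulated annealing; valid solutions are reconstructed into
    docked compound poses and scored by redocking RMSD. A synthetic instance
    generator with planted ground-truth solutions supports end-to-end testing
    and solver benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    ChemmineR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: OpenBabel (obabel, obenergy, obminimize on PATH)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
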