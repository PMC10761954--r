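Package: racekin
Title: Kinetic Modeling of Transaminase Futile Cycles and Amine Racemization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modeling the racemization of chiral amines by
    amine transaminases. Builds second-order mass-action ODE systems over
    amine/ketone species and the two cofactor states of the enzyme (E-PLP
    and E-PMP), integrates them with stiff solvers, detects stereoinversion
    onset and racemization completion, scans kinetic stereoselectivity,
    estimates second-order rate constants from replicate initial-rate
    assays, and triages docking poses with nucleophilic-attack-trajectory
    (NAT) geometry criteria. Includes seeded generators for chiral-HPLC-like
    time courses, initial-rate assays, enantio-impure stocks and PDB pose
    fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    graphics,
    utils,
    tools,
    yaml,
    jsonlite,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
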