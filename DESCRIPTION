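Package: paosim
Title: Musculoskeletal and Finite-Element Co-Simulation of Periacetabular
    Osteotomy Screw Fixation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale co-simulation pipeline for evaluating screw fixation
    of the acetabular fragment after periacetabular osteotomy (PAO).
    Generates synthetic gait trials and parametric hemipelvis-fragment-screw
    geometry, normalizes gait to the cycle and segments Rancho Los Amigos
    phases, performs inverse dynamics with polynomial (min-sum (f/N)^p)
    muscle recruitment to obtain hip joint reaction forces, maps CT
    Hounsfield units to bone density and elastic modulus, solves linear
    tetrahedral finite-element models with bonded screws and a callus-
    weakened osteotomy margin, and runs peak-stress statistics, mesh
    convergence, and incremental yield-load failure analysis comparing
    fixation layouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    Matrix,
    jsonlite,
    ggplot2,
    generics,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS
Config/testthat/edition: 3
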