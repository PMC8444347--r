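Package: gugaci
Title: Spin-Adapted Configuration Interaction with Stochastic Reduced Density Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for spin-adapted configuration interaction in the
    graphical unitary group approach (GUGA). Builds configuration state function
    (CSF) bases as distinct row tables, evaluates spin-free unitary-group generator
    matrices and Hamiltonians, and solves them either by exact diagonalization or by
    a full configuration interaction quantum Monte Carlo (FCIQMC) stochastic
    eigensolver with semistochastic projection. Two-replica walker dynamics provide
    unbiased stochastic sampling of spin-free one- and two-body reduced density
    matrices, from which local spin expectation values, fragment spin sums, and
    orbital-resolved spin-spin correlation functions are computed. Spin ladders can
    be mapped onto bilinear and biquadratic Heisenberg models by least-squares
    fitting with a relative-error quality measure. Includes FCIDUMP integral I/O,
    Hubbard and antiferromagnetic exchange-cluster model builders, and exact
    spin-model (Heisenberg) diagonalization oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
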