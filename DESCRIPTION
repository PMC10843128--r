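Package: infodecomp
Title: Generalized Information Decomposition over Redundancy Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decomposing multivariate information in discrete
    systems. Implements the partial entropy decomposition (PED) of joint
    and local entropy over the Williams-Beer redundancy (antichain)
    lattice with the h_min redundancy function, and a generalized
    information decomposition (GID) that splits the Kullback-Leibler
    divergence between an arbitrary prior and posterior into lattice
    atoms. Derived decompositions include total correlation, negentropy,
    cross entropy, single-target partial information decomposition (PID),
    and atom-level expansions of the O-information and the
    Tononi-Sporns-Edelman (TSE) complexity. Distributions and atom tables
    are tibbles throughout; fixtures (logic gates, giant bit, seeded
    Dirichlet distributions) and a small command-line interface are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
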