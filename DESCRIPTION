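Package: grnmem
Title: Zwanzig-Mori Projection and Memory Functions for Gene Regulatory
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reduces thermodynamic state-ensemble models of transcriptional
    regulation to the dynamics of a chosen subnetwork. The influence of the
    remaining species (the bulk) is captured by memory functions obtained
    from a Zwanzig-Mori projection of the dynamics linearised or expanded to
    quadratic order around a steady state. Includes the expansion of a
    thermodynamic model into a mass-action network of protein and
    DNA-conformation species with detailed-balance rate constants, the
    quasi-steady-state elimination that proves the projection can be
    computed from the thermodynamic equations alone, Volterra integration of
    the closed projected equations, memory amplitude and bulk-channel
    decomposition, and steady-state continuation, basin-of-attraction and
    link-removal analyses of multistable gene circuits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
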