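Package: rexfit
Title: Two-Site Chemical-Exchange Analysis of NMR Relaxation Dispersion Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of CPMG and R1rho NMR relaxation dispersion data with
    two-site chemical-exchange models. Converts peak intensities to effective
    transverse relaxation rates, fits the classical analytic dispersion models
    (LM63, CR72, IT99, TSMFK01, MMQ-CR72, M61, DPL94, TP02, MP05) as well as
    numeric solutions of the Bloch-McConnell equations, and provides an
    automated protocol with warm-started sequential optimisation, fixed model
    elimination rules, Monte-Carlo error propagation and AIC model selection
    over spin clusters that share exchange kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
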