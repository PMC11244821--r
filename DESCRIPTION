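Package: madfe
Title: Distribution of Mutational Effects from Mutation-Accumulation
    Microcolony Growth Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers the distribution of fitness effects (DFE) of spontaneous
    mutations on microbial growth rate from mutation-accumulation (MA)
    microcolony experiments. Per-strain selection coefficients and petite
    (respiration-deficient) subpopulation proportions are estimated from
    paired MA-vs-reference colony growth-rate differences under a
    four-component Gaussian mixture that cancels plate and well batch
    effects, with profile-likelihood confidence intervals and
    false-discovery-rate significance calls. Compound-Poisson
    reflected-gamma models of single-mutation effects (with optional
    Gaussian or second-gamma components for unidentified mutations) are
    fitted in the Fourier domain via characteristic functions and the FFT,
    either to per-strain summary statistics or to the complete paired
    colony data, with AIC and likelihood-ratio model comparison. A
    synthetic-data generator reproduces the full hierarchical structure of
    the assays (strains, plates, wells, imaging fields, petite controls)
    for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
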