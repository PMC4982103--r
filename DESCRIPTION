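Package: chelapower
Title: Catalytic Power and Free-Energy Transduction of Magnesium Chelatase
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of ATP-coupled magnesium insertion into
    porphyrins by magnesium chelatase. Provides a deterministic ODE model of
    chelation with uncatalyzed dechelation, nucleotide depletion and an
    ATP-regeneration system; through-origin fitting of the first-order
    dechelation rate constant from initial rates; derivation of the
    uncatalyzed second-order chelation constant, rate enhancement, catalytic
    proficiency, transition-state affinity and thermodynamic displacement
    from equilibrium; a stochastic model of probabilistic coupling between
    ATPase cycles and metal insertion; and seeded synthetic-data generators
    emulating the fluorescence plate-reader assays.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
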