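Package: rgcprog
Title: State-Transition Modeling of Retinal Ganglion Cell Dysfunction and Death
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling progressive retinal ganglion cell (RGC)
    dysfunction and death in glaucoma and other optic neuropathies. Provides a
    closed-form three-compartment (healthy/sick/dead) decay model with a
    deterministic sick-to-dead lag, an equivalent discrete-time stochastic
    state-transition simulator generalizing to a seven-stage scheme, an
    observation model mapping latent function and population indices to
    pattern electroretinogram (PERG) and optical coherence tomography (OCT)
    style measurements with noise and a response floor, least-squares
    parameter estimation with bootstrap intervals and treatment-window
    biomarkers (horizontal window, vertical dysfunction gap), and
    PERG-dynamics indices (contrast gain, adaptation, susceptibility,
    resilience) with intervention-pattern classification. Includes a
    synthetic-data generator emulating DBA/2J mouse natural-history series
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
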