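Package: histasim
Title: Kinetic Simulation of a Histamine Varicosity with Autoreceptor Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic kinetic model of histamine neurotransmission at a
    single varicosity: histidine transport from blood, histamine synthesis by
    histidine decarboxylase, vesicular packaging, firing-driven release,
    reuptake, glial catabolism, and an H3-autoreceptor transduction loop
    (G-protein subunit plus RGS protein) that feeds back on release and
    synthesis. Provides a stiff ODE simulator with piecewise-constant firing
    and dietary-input protocols, steady-state solving with flux-balance
    audits, and reproducible in-silico experiments: synthesis-blockade
    half-life, histidine loading, dietary interventions, stimulation with and
    without autoreceptor blockade, enzyme-polymorphism perturbations, and an
    oscillatory parameter variant. Results come back as tibbles with tidy(),
    glance(), and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
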