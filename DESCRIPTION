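Package: newswaves
Title: Analytic SIR Waves for News and Information Diffusion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the spread of a piece of news through a population with
    the SIR (susceptible-infected-removed) compartmental model and a family
    of closed-form wave solutions obtained by truncating the exponential
    nonlinearity of the removed-compartment equation at polynomial order M.
    Provides the quadratic (Riccati, hyperbolic-tangent) and cubic
    closed-form trajectories, an adaptive numerical integrator of both the
    full SIR system and the truncated polynomial chain as oracles, Taylor
    truncation validity bounds, wave metrics (amplitude, time horizon,
    effective reproduction number crossing), a transmission/recovery rate
    wave typology, a composer for wavetrains of successive news waves, and
    shipped parameter scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
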