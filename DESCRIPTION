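Package: glvsim
Title: Random Community Assembly and Viability under Generalized Lotka-Volterra Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying the viability of large random
    model ecosystems. Samples random per-capita interaction matrices with
    prescribed richness, connectance and interaction-strength scale, builds
    generalized Lotka-Volterra (GLV) communities around a guaranteed interior
    equilibrium, evaluates local stability from the Jacobian spectrum, and
    follows perturbed trajectories under both the classical GLV model and a
    bounded variant in which per-capita growth is attenuated towards an
    abundance ceiling. Replicated richness sweeps quantify the proportion of
    stable communities, the frequency of population blow-up, species
    persistence, and the ecological selection of positive interactions, with
    two-species phase-plane tools for the bounded model. Results are returned
    as tibbles with broom-style tidiers and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
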