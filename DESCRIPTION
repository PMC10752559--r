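Package: cheatnet
Title: Cheating Dynamics in Mutualistic Plant-Pollinator Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized Lotka-Volterra simulation of bipartite plant-pollinator
    communities in which pollinators may cheat (rob nectar) either conservatively,
    on existing mutualistic partners, or innovatively, on plants outside their
    mutualistic niche. Provides synthetic community generation, saturating
    functional responses with within-guild interference, equilibrium integration
    with stability and persistence scoring, structural network metrics (NODF
    nestedness, Barber bipartite modularity via label propagation), parameter
    sweeps with matched no-cheating baselines and variance decomposition, a
    synthetic camera-trap field-data generator over an elevation gradient, the
    empirical cheating-pattern estimators (including a weighted 2D kernel-density
    estimate of the innovative proportion), and model parameterization from
    empirical networks with cheating-pattern randomization and z-scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    vegan,
    car
Config/testthat/edition: 3
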