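Package: leakytoggle
Title: Stability, Robustness and Population Heterogeneity of Genetic Toggle
    Switches with Leaky Promoters and Shared Resources
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the dimensionless genetic toggle switch with
    promoter leakiness and competition for shared transcriptional and
    translational resources, both inside the switch and from its genetic
    context. Locates and classifies equilibria (monostable, bistable,
    tristable), maps stability classes over parameter grids and fits the
    linear region boundaries, computes the quasi-potential epigenetic
    landscape along trajectories and the potential barriers separating
    metastable states, fits the barrier power law in the composite statistic
    q = 2(1+beta)/alpha, simulates overdamped Langevin dynamics
    (Euler-Maruyama) to estimate switching statistics, models cell-to-cell
    heterogeneity by correlated normal parameter distributions with analytic
    and Monte-Carlo stability fractions, and quantifies how burden from the
    genetic context reshapes stability and robustness through an exact
    parameter rescaling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
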