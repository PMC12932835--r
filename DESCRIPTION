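Package: rangecast
Title: Dynamic Occupancy Modelling and Forecasting of Species Range Expansion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Fits a two-state dynamic occupancy model for species range
    expansion on a gridded landscape. Persistence and colonization are
    modelled as complementary log-log hazards with the survey interval as
    an offset, and dispersal limitation enters through the distance from
    each cell to the nearest occupied cell, recomputed at every transition.
    Includes a synthetic-landscape simulator with known truth, Bayesian
    estimation by adaptive Metropolis-within-Gibbs with Gelman-Rubin
    diagnostics, support for a final presence-only survey occasion, and
    forward Monte-Carlo forecasting of occupancy probability maps under
    covariate scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
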