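Package: presymscan
Title: Presymptomatic Spatial Cluster Scanning of Residential Histories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for geo-epidemiological analysis of disease cohorts in the
    decades preceding clinical onset. Reconstructs patient locations from
    residential histories at yearly offsets before onset, builds populations
    at risk from sparse census tables (with intercensal interpolation and
    indirect sex/age standardization), and runs a Kulldorff-type circular
    spatial scan with a Poisson likelihood ratio statistic and Monte Carlo
    inference at each offset. Also provides a capacity-weighted Monte Carlo
    null for unrelated patients co-residing in the same dwellings, with
    capacity-stratified restriction analysis, and synthetic registry
    generators (region, census, cohort, dwelling stock) so the whole pipeline
    can be exercised and validated without access to confidential registry
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
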