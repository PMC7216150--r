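Package: peerwell
Title: Peer Nomination Networks and Academic Well-Being in School Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing sociometric peer-nomination surveys in school
    cohorts: reading and validating rosters, bounded nomination edge lists and
    survey item responses; scoring short schoolwork-engagement, school-burnout,
    school-connectedness and family-affluence scales with complete-case rules
    and Cronbach's alpha; building directed within-school nomination networks
    and computing ego-level position (social activity, popularity, isolation)
    and school-level structure (density, Freeman degree centralization,
    average ego clustering); and fitting standardized multilevel
    random-intercept regressions of academic well-being on network position
    and structure. Includes a calibrated synthetic school-cohort generator
    with planted effects so the whole pipeline can be verified end to end by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    car,
    yaml
Config/testthat/edition: 3
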