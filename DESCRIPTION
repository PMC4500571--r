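Package: bswitch
Title: Bistable Switch Analysis of the B-Lymphoid Lineage Commitment Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ordinary differential equation models of the gene regulatory
    network that commits lymphoid-primed multipotent progenitors (LMPPs) to
    the B-lymphoid lineage, centred on the mutual antagonism between ZNF521
    and the EBF1/E2A/PAX5 axis. Provides the full ten-species network, its
    seven core feedback sub-modules and alternative-topology variants behind
    a uniform right-hand-side/Jacobian interface; time integration,
    multi-start equilibrium finding, linear stability classification and 2-D
    nullclines; pseudo-arclength continuation with fold (limit point)
    detection and classification of the commitment switch as monostable,
    reversible bistable or irreversible bistable; one-at-a-time parameter
    sweeps for preservation of bistability; a genetic-algorithm search for
    bistable parameter sets; reprogramming-schedule simulation; and
    comparison of model attractors with synthetic two-condition expression
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
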