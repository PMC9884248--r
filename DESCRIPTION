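Package: roadaccess
Title: Population Accessibility to Public Services and Road Criticality
    Under Hazard Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: User-centric measurement of population accessibility to public
    service facilities (healthcare as the demonstration sector) over a road
    network, in baseline, single-hazard and compound-hazard scenarios.
    Builds an annotated road graph, snaps facilities, samples population
    origins, disrupts the network with flood and fault-line hazard layers
    via speed penalization or full link disruption, and computes
    Huff-model facility-choice probabilities, expected access times,
    preference-weighted road-segment criticality, and isolated population.
    Includes a fully synthetic city generator so the entire pipeline can
    be exercised without external data, scenario comparison via
    Jensen-Shannon divergence and destination-preference shifts, and an
    influence-radius subgraph partitioning scheme for large networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
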