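Package: streetaudit
Title: Gap-Filling and Temporal Validation of GIS Layers with Historic
    Street-Level Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for auditing the completeness and temporal validity of
    municipal GIS layers using date-filtered historic street-level imagery,
    organised around child-specific activity spaces. Builds road-network
    graphs from polyline layers with linear referencing, shortest-path
    routing and network (service-area) buffers; constructs per-participant
    activity spaces from home, nearest school and the home-school route;
    samples audit coordinates at fixed intervals along the network; plans
    four-heading image requests with an in-range capture-date filter against
    a pluggable panorama provider; ingests coder observation checklists;
    synthesises point and line feature layers, gap-fills council layers and
    computes validation statistics. A seeded synthetic-town generator
    emulates the study inputs (road network, dated streetscape features,
    council exports with omissions and anachronisms, panorama availability,
    a coder oracle) so the whole pipeline runs with no external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
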