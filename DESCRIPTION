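Package: scaleaccess
Title: Multiscalar Spatial Accessibility Index for Primary Health Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes the SCALE index, a multiscalar floating-catchment
    measure of potential spatial accessibility to primary health care.
    For each residential area and facility type it derives a potential
    accessibility area (ZAP) from the longest nearest-facility travel
    time within the enclosing census unit (IRIS), weights travel costs
    to the facilities in that area by the demand pressure estimated from
    a travel-cost Voronoi assignment of population, transforms the
    resulting potential accessibility distances to standard-normal
    scores, and combines them linearly into a single index with decile
    categorization. Includes origin-destination travel costs on a road
    network or by straight line, aggregation of the index to larger
    units under four criteria with between-version agreement statistics,
    and a reproducible synthetic-geography generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
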