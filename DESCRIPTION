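Package: odtcube
Title: Origin-Destination-Time Cubes for Human Mobility Flows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts origin-destination-time (ODT) human mobility flows
    from geotagged event streams and home-based device-count mobility
    records, organises them as a sparse multi-scale ODT data cube with
    slice, dice and roll-up query operations, exports flows in a flat CSV
    dialect, and supports downstream epidemiological analyses: monthly
    mobility reduction rates against a baseline period and daily
    correlation between place outflows and confirmed case counts. Includes
    a seeded synthetic-data generator (nested grid geographies, random-walk
    event streams, home-based flow records, planted case counts) with an
    independent ground-truth oracle so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
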