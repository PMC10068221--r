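Package: e2svca
Title: Telehealth Accessibility with Floating and Virtual Catchment Area Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures spatial and virtual (telehealth) accessibility to
    health care with the two-step floating catchment area family of models:
    2SFCA, the binary-broadband 2SVCA, and the enhanced E2SVCA, which weights
    each demand-supply pair by a step-wise function of the minimum of the four
    broadband speeds (patient up/down, provider up/down).  Includes per-block
    aggregation of multi-provider broadband speeds (average, minimum
    available, minimum/maximum of the most frequent speeds), travel-time
    catchments on road graphs, a deterministic synthetic study-area
    generator, score normalization and classification, method comparison,
    and CSV/GeoJSON input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
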