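Package: lithicedd
Title: Assemblage-Scale Edge Damage Distribution Analysis for Lithic Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts digitized stone-tool outlines and edge-damage scar
    polygons into standardized 400-position presence/absence damage vectors
    (platform-to-tip arc-length percent intervals on four edges), aggregates
    them into assemblage-scale edge damage distributions with loess smoothing,
    compares distributions with Kolmogorov-Smirnov and chi-square balance
    tests, and identifies which experimental damage-formation processes
    (armature use, butchery, trampling, tumbling) best explain an
    archaeological distribution via forward-stepwise ordinary least squares
    under the small-sample-corrected Akaike information criterion (AICc) with
    a delta-AICc < 2 parsimony rule. Includes a synthetic generator for
    pointed-tool outlines, process-specific damage patterns, random uniform
    distributions, and known mixtures, plus readers/writers for GeoJSON tools
    and the tool-by-position matrix and distribution-table CSV layouts, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
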