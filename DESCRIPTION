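Package: tendermcda
Title: Multi-Criteria Decision Analysis for Off-Patent Medicine Tenders
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A configurable multi-criteria decision analysis (MCDA) engine
    for two-phase pharmaceutical tenders of off-patent (generic) medicines.
    Criterion weights are elicited from stakeholder vote panels by SMART
    swing-weighting with median aggregation; product bids are scored on
    weighted categorical criteria with hard exclusion triggers and a
    qualification threshold; qualified bids are ranked by price per point
    within each active ingredient. Includes a synthetic-data generator for
    bids and vote panels with known ground truth, command-line style entry
    points, and the published Egyptian UPA oncology-tender configuration as
    the default.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
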