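Package: bwsqol
Title: Best-Worst Scaling Counting Analysis with ISAC Segmentation for
    Quality-of-Life Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes single-task, full-profile best-worst scaling (MaxDiff)
    surveys of quality-of-life priorities. Provides response cleaning with an
    auditable removal report, descriptive demographic tables under explicit
    denominator conventions, best-minus-worst counting scores with normalized
    relative weights and a tie-corrected Friedman test on implied ranks,
    demographic segmentation with chi-square contrasts, deterministic
    persona construction, and a latent-utility synthetic respondent generator
    with segment-dependent preference shifts for validating every pipeline
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
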