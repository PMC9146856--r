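Package: capsulevq
Title: Machine Scoring of Bubble Abundance and Cleanliness in Small-Bowel
    Capsule Endoscopy Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-by-frame quality scoring of small-bowel capsule endoscopy
    recordings: a grey-level co-occurrence matrix (GLCM) contrast detector
    classifies frames as scarce or abundant in bubbles, and a red-over-green
    colorimetric ratio classifies frames as adequately or inadequately
    cleansed. Scores are aggregated per quartile of the small-bowel sequence
    and compared between two preparation arms with a two-way mixed
    repeated-measures ANOVA, Welch t-tests and chi-square tests. Includes a
    synthetic frame and cohort generator with planted ground truth (circular
    field of view, controllable bubble coverage and red/green balance) so the
    whole pipeline is testable without real recordings, plus a screening
    filter reproducing a study flow chart.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
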