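Package: ccecleanse
Title: Bowel-Cleansing Quality Grading and Rater Agreement for Colon Capsule Endoscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated bowel-cleansing quality assessment in colon
    capsule endoscopy (CCE). Classifies frame pixels as clean or dirty with a
    configurable HSV-threshold rule, reduces frames to clean-pixel fractions
    and continuous cleanliness ratings, summarizes rating streams with mean,
    median, quartile and extreme-percentile statistics, and maps summaries to
    the 4-point Leighton-Rex scale and a 2-point acceptability scale. Supports
    flexure-based colon segmentation, 5-to-3 segment merging of human reader
    grades, overall-acceptability rules, and interobserver agreement analysis
    (percent agreement, Cohen's kappa, weighted kappa with asymptotic and
    bootstrap confidence intervals, interpretation bands). Includes a seeded
    synthetic-data generator producing frames, rating streams and correlated
    reader reports so the full pipeline is testable without raw videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
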