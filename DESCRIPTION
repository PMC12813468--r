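Package: longiheat
Title: Longitudinal Brain-Feature Heatmaps for Dementia Stage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing longitudinal structural-MRI scalar features
    (gray matter, white matter, cerebrospinal fluid and white-matter
    hyperintensity volumes, and mean cortical thickness) across the dementia
    spectrum (cognitively normal through mild cognitive impairment tiers to
    Alzheimer's disease). Session-level feature tables are encoded as
    28-bin, 3-channel, bit-depth-quantized time heatmaps; small convolutional
    and fully convolutional networks classify the five diagnostic groups;
    gradient-weighted class activation maps localise the time bins driving
    each decision; and a nonparametric statistics layer (Shapiro-Wilk
    screening, Kruskal-Wallis omnibus tests, Benjamini-Hochberg adjustment)
    compares groups. A synthetic-cohort generator parameterized by published
    per-group baseline and annual-change statistics makes every stage
    testable without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    yaml,
    png
Config/testthat/edition: 3
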