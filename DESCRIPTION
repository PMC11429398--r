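Package: hawkfs
Title: Harris Hawks Wrapper Feature Selection with Canonical Correlation
    Feature Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying samples described by two deep-feature views,
    as in histopathology image analysis of oral squamous cell carcinoma.
    Implements canonical correlation analysis (CCA) fusion of two feature
    views, continuous Harris Hawks optimization (HHO) and its improved
    elite-update variant (IHHO), the binary wrapper b-IHHO that selects
    feature subsets through a k-nearest-neighbour fitness, a synthetic
    two-view data generator with known ground truth, and a multi-run
    comparison harness (pooled two-sample t-test, Cohen's d, box summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    class,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
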