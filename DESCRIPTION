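Package: fruitview
Title: Fruit Detectability from Multiple Camera Viewpoints in Occluded Canopies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how camera placement affects fruit detection in
    dense crop canopies. Implements per-viewpoint fruit detectability (FD) under
    fruit-visibility (FV) thresholds, the sample standard deviation of FD across
    plants, exhaustive enumeration of multi-viewpoint combinations with
    maximum-FD-per-subset-size and positions-needed summaries, and a greedy
    set-cover alternative for large viewpoint sets. A seedable synthetic canopy
    simulator generates crop-row scenes (fruit spheres, elliptical leaf
    occluders) and computes per-fruit visibility by Monte-Carlo ray casting, so
    the full analysis pipeline can be exercised and validated without field
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
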