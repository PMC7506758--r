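Package: camoscore
Title: Camouflage Effectiveness Scoring from Perceived Color and Texture Differences
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how conspicuous a camouflage pattern is against a set
    of background images. Color differences are computed in S-CIELAB space,
    the spatial extension of CIELAB that low-pass filters opponent color
    channels according to the observer's viewing distance, and pooled as the
    population standard deviation of the per-pixel color difference (ICSI).
    Texture differences are computed from Sobel gradient magnitudes as the
    gradient magnitude similarity deviation (GMSD). The two metrics are fused
    by the information-entropy weight method into a single conspicuousness
    score per pattern, where lower scores indicate more effective camouflage.
    Includes image input/output, viewing-geometry conversion, a seeded
    synthetic stimulus generator, batch scoring with persisted difference
    matrices, and correlation of scores against subjective detection data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
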