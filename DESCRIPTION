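Package: leaftaper
Title: Half-Leaf Width Taper Models and the Tipping Leaf Length Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of single-vein (conifer) leaves under the
    assumption of bilateral symmetry about the midrib. Extracts half-width
    profiles along the base-to-tip axis from binary leaf masks, fits the
    quadratic taper model Y = C + B1*X + B2*X^2 to half-width versus position,
    derives the vertex (position of maximum width) and the tipping leaf length
    ratio (vertex position over total length), and compares leaf cohorts with
    descriptive summaries and one-way ANOVA with Fisher LSD compact letter
    displays. Includes a synthetic leaf-shape generator with known ground
    truth (quadratic, ovate, oblong and elliptic families), a 600-dpi mask
    renderer for round-trip validation, and a reproducible simulate-extract-
    fit-summarize pipeline with a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tibble,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
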