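Package: lumiqc
Title: Machine Scoring of Colonoscopy Luminal Visualization Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Frame-level no-reference sharpness scoring of endoscopy video
    using a steerable Gaussian-derivative filter bank (the SFIL focus
    measure), ordinal threshold calibration onto a four-point quality scale
    (poor, almost poor, almost good, good), clip-level band estimation with
    out-of-body frame flagging, and rater-agreement statistics
    (Goodman-Kruskal gamma, exact Wilcoxon signed-rank, band-difference
    tables). Includes a synthetic phantom-frame generator emulating
    endoscopic scenes at controlled blur levels so the full pipeline is
    testable without clinical video.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
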