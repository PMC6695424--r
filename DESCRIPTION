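Package: twitchindex
Title: Contractility and Myokine Response Analysis for Electrically
    Stimulated Myotube Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies electric-pulse-stimulation (EPS) evoked contractile
    activity of cultured myotubes from time-lapse image stacks using the
    differential image subtraction movement index, quantifies the composition
    of human-mouse hybrid myotubes (human-nuclei ratio from two-channel masks,
    satellite-cell marker gating), and performs species-resolved myokine
    response statistics (reference-gene qPCR normalization, limit-of-detection
    censoring, cross-reactivity exclusion, and t-test classification of a
    40-analyte secretion panel). A synthetic-data module generates every input
    with known ground truth so the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
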