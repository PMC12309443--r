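Package: penguinsong
Title: Rhythm and Intensity Analysis of African Penguin Display Songs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify accelerando and crescendo in the ecstatic
    display songs of African penguins (Spheniscus demersus). Reads Praat
    TextGrid syllable annotations or CSV syllable tables, computes
    inter-onset intervals, silent intervals, acceleration ratios and
    small-sample-corrected coefficients of variation, decides via a kernel
    density likelihood comparison whether ingressive (breath) syllables
    take part in a song's temporal stream, and fits the full nested
    linear mixed-effects inference suite with likelihood-ratio tests,
    per-penguin regressions, and a modified signed-likelihood ratio test
    for equality of coefficients of variation. A synthetic song generator
    with the same statistical structure makes every stage testable
    without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
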