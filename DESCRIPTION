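Package: daphtrack
Title: Movement Track Analysis for Behavioral Ecotoxicology of Daphnia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying swimming behavior of the water flea
    Daphnia magna (and similar small aquatic organisms) from 2-D video
    tracking coordinates. Trajectories are segmented into fixed time
    windows; seven instantaneous movement parameters (speed, acceleration,
    locomotory rate, stop number, stop time, turning rate, meander) are
    computed per 5-second segment; the box-counting fractal dimension of
    rasterized 10-minute tracks summarizes overall movement complexity; a
    sequential Kohonen self-organizing map with Ward clustering of the
    codebook classifies segments into six canonical movement patterns
    (line, loop, cross, shaking, swirl, stay); and paired one-tailed
    t-tests compare behavior before and after a chemical treatment. A
    seeded correlated-random-walk generator produces synthetic archetype
    segments and full before/after observation sessions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
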