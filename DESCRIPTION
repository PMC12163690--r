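Package: motivenets
Title: Idiographic Motive-Satisfaction Networks from Experience-Sampling Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating per-person contemporaneous partial-correlation
    networks of momentary motive satisfaction from beep-level experience-sampling
    (ESM) records, summarising each network with signed concordance and discordance
    indices (conflict proportion, maximum conflict, maximum concordance), and
    relating those indices to depressive symptoms with bias-corrected and
    accelerated (BCa) bootstrap inference and a hybrid random-intercept mixed
    model. Includes a calibrated synthetic-data generator that emulates the beep
    grid, missingness, and between-person structure such studies produce, so the
    full pipeline is testable without raw participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lme4,
    lmtest,
    MASS,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
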