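Package: pupilrps
Title: Decoding Concealed Rock-Paper-Scissors Choices from Pupil Dilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates decision-locked pupil-diameter traces for concealed
    rock-paper-scissors choices, decodes the choice from the time of maximum
    pupil dilation, simulates player strategies against the decoded signal,
    and computes the associated exact-binomial and t-test statistics,
    including sequential (learning-curve) significance boundaries. Includes
    a calibrated synthetic-trace generator with exact control over marker
    validity, a deterministic 75-game reference fixture, and CSV/JSON
    readers and writers for traces and game manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
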