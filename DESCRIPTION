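Package: arrowsim
Title: Agent-Based Simulation of Social Learning in the Virtual Arrowhead Task
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the virtual arrowhead task used in experimental
    studies of cultural evolution. Agents tune the attributes of a virtual
    arrowhead on a season-structured, additive, unimodal fitness landscape
    with Gaussian perception noise, learning either asocially (the Win-Stay
    rule) or socially (copy-successful-individuals and Reverse, a negative
    observational learning rule). Includes the exemplar ("other hunter")
    generation procedure with rejection resampling for positive and
    negative social information, cohort simulation with trajectory
    summaries, a synthetic trial-level data generator, and the analysis
    pipeline (Welch t-tests with Bonferroni correction, Cohen's d, F-tests
    of variance equality, one-sample t-tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    ggplot2,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
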