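Package: eshval
Title: ESH-IP2 Blood Pressure Device Validation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the European Society of Hypertension International
    Protocol revision 2010 (ESH-IP2) analysis for validating automated blood
    pressure monitors against a reference device: the nine-reading alternating
    measurement schedule, favorable flanking-reference pairing, cumulative
    band classification of paired differences, Part 1 / Part 2 / Part 3
    grading for systolic and diastolic pressure and a heart-rate extension,
    and Bland-Altman agreement summaries. Includes a synthetic-cohort
    generator with configurable physiology and device error models, and
    Monte-Carlo estimation of protocol pass probabilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
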