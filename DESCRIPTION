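Package: pharmnetrisk
Title: Patient-Safety Risk Assessment for Medicines Sold on the Internet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable risk-assessment toolkit for online pharmaceutical
    market surveillance. Scores medicinal products on a five-dimension
    patient-safety rubric (general pharmaceutical, therapeutic,
    microbiological-contamination, augmented-demand, and counterfeiting risks),
    converts recorded search-engine result ledgers into a probability of
    online purchase (availability x affordability), and combines the two in a
    severity-by-probability risk matrix that ranks products and selects
    test-purchase candidates. Ships a worked ten-product ophthalmic fixture
    set and a seeded synthetic generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
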