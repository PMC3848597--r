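Package: slsagree
Title: Agreement Analysis of Retail-Audit and Recall Sales Volume Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for sales-level surveys (SLS) of anti-malarial medicines
    and rapid diagnostic tests in commercial outlets. Converts raw
    outlet-level stock and sales records into standardized volumes (adult
    equivalent treatment doses for anti-malarials, single test units for
    RDTs), computes retail-audit (stock-flow) sales estimates, pairs them
    with provider-recall estimates under explicit exclusion rules, and
    quantifies between-method agreement with the Bland-Altman procedure:
    bias, limits of agreement with confidence intervals, proportional-bias
    correlation, normality diagnostics and mean-difference plots. Includes
    a synthetic-survey generator with configurable recall-bias,
    counting-error, nonresponse and outlier mechanisms so that every stage
    of the pipeline can be validated without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    ggplot2,
    jsonlite,
    readr,
    stats,
    tools,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
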