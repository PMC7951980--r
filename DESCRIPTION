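Package: transcreen
Title: Rule-Based Screening of Transparency Indicators in Biomedical Full Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects five indicators of research transparency (data sharing,
    code sharing, conflict-of-interest disclosure, funding disclosure, and
    protocol registration) in biomedical full-text articles using editable
    rule lexicons with masking, localization, and negation. Reads JATS/NLM
    XML and plain text into a zone-labelled document model, screens whole
    corpora into flat per-article records, and aggregates prevalence across
    years, journals, publishers, and countries. Includes the validation
    machinery for such screeners: confusion-matrix diagnostics, stratified
    importance-sampling estimation of error rates, nonparametric bootstrap
    confidence intervals, and PPV/NPV-adjusted prevalence, together with a
    synthetic-article generator that plants indicator statements with truth
    manifests for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    parallel,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
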