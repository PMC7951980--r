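# transcreen

Rule-based screening of biomedical full text for five indicators of
research transparency: **data sharing**, **code sharing**,
**conflict-of-interest (COI) disclosure**, **funding disclosure**, and
**protocol registration**.

Manually auditing open-science practice does not scale to a literature
growing by tens of thousands of articles per week. `transcreen` reads
full-text articles (JATS/NLM XML as distributed by PubMed Central, or plain
text from PDF conversion) into a zone-labelled document model and screens
them with editable regular-expression lexicons organised into labelling,
masking, localization, and negation rules. Every detection reports three
things: *whether* an indicator statement is present, *why* (which lettered
category of rule fired, e.g. "field-specific database" or "no-funding
statement"), and the *verbatim evidence* sentence or paragraph — so results
are always auditable and redefinable downstream.

The package also ships the statistics needed to validate such a screener
against manual labels, and a synthetic-article generator for end-to-end
testing without any downloads:

* `read_jats()`, `read_plaintext()`, `locate_section()`,
  `xml_tagged_indicators()` — document ingestion and the tag-only baseline;
* `normalize_text()`, `tokenize_text()`, `apply_masks()` — preprocessing
  (custom sentence tokenizer with abbreviation guards; length-preserving
  masking);
* `detect_data_sharing()`, `detect_code_sharing()`, `detect_coi()`,
  `detect_funding()`, `detect_registration()` — the five detectors;
* `screen_article()`, `screen_corpus()`, `standardize_labels()`,
  `prevalence_by()`, `centered_moving_average()` — corpus screening and
  aggregation;
* `diagnostic_metrics()`, `weighted_rate()`, `adjusted_prevalence()`,
  `bootstrap_ci()` — validation statistics. The importance-sampling
  estimator reweights stratified samples of a large predicted-negative pool,
  `sum(N_h/n_h * positives_h) / sum(N_h)`; an observed flag rate `p` is
  corrected for detector error as `p*PPV + (1-p)*(1-NPV)`;
* `generate_article()`, `generate_corpus()`, `template_bank()` — synthetic
  JATS corpora with planted statements and truth manifests.

## Worked example

```r
library(transcreen)

# a synthetic corpus with known truth: 200 articles at realistic prevalences
corpus <- generate_corpus(200, seed = 42)
records <- screen_corpus(corpus$documents, format = "jats", quiet = TRUE)

records[1, c("article_id", "is_coi_pred", "is_fund_pred", "coi_text")]
#> # A tibble: 1 × 4
#>   article_id     is_coi_pred is_fund_pred coi_text
#>   <chr>          <lgl>       <lgl>        <chr>
#> 1 synthetic-0001 TRUE        TRUE         The authors declare no competing inte…

prevalence_by(records)[, c("n_total", "coi_prop", "fund_prop", "data_prop")]
#> # A tibble: 1 × 4
#>   n_total coi_prop fund_prop data_prop
#>     <int>    <dbl>     <dbl>     <dbl>
#> 1     200    0.775     0.825      0.14

# validate the screen against the generator's truth manifest
m <- diagnostic_metrics(confusion_counts(corpus$manifest$coi_truth,
                                         records$is_coi_pred))
m
#> <diagnostics> n=200  tp=155 fp=0 fn=0 tn=45
#>   sensitivity 1.000  specificity 1.000  ppv 1.000  npv 1.000  accuracy 1.000
#>   prevalence true 0.775 / estimated 0.775  (error 0.000)

# correct an observed flag rate for detector error
adjusted_prevalence(0.686, ppv = 0.97, npv = 0.95)
#> [1] 0.68112
```

The per-article record also carries one boolean per rule category
(`coi_a` … `coi_e`, `fund_a` … `fund_h`, …), subtype fields
(`no_conflict`/`conflict_declared`, `no_funding`/`funds_received`), and any
captured registry identifiers (NCT, CRD, ChiCTR, …), so consumers can apply
their own, stricter definitions of each indicator without re-screening.

A thin command-line front end is installed at
`system.file("cli", "transcreen.R", package = "transcreen")` with
`screen`, `aggregate`, `validate`, and `simulate` subcommands.

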