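---
title: "Screening biomedical full text for transparency indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening biomedical full text for transparency indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transcreen)
```

## The problem

Manual audits of open-science practice do not scale: tens of thousands of
biomedical articles appear each week, and whether an article discloses
conflicts of interest, declares its funding, registers its protocol, or
shares its data and code is buried in free text that every journal phrases
differently. `transcreen` screens full-text articles for five indicators of
transparency — **data sharing**, **code sharing**, **conflict-of-interest
(COI) disclosure**, **funding disclosure**, and **protocol registration** —
using interpretable rule lexicons rather than a trained black box. Every
flag it raises is accompanied by the category of rule that fired and the
verbatim sentence or paragraph that triggered it, so a human can always
audit *why* an article was labelled.

This vignette explains the document model, the text-processing decisions,
the detector design, the validation statistics, and what the synthetic
corpus generator does and does not establish.

## Document model and zones

Articles enter as JATS/NLM XML (the PubMed Central open-access dialect) or
as plain text from PDF conversion. Both are reduced to an ordered set of
*text units*, each labelled with a zone: `title`, `abstract`, `body`,
`heading`, `acknowledgments`, `footnote`, or `back_other`. Two structural
rules are enforced at construction:

* **Reference lists are never units.** Citation text is a notorious source
  of false positives ("...data sharing in clinical trials. *BMJ* 2017"),
  so it is excluded at parse time rather than filtered later.
* **Table and figure captions are flagged** (`display = TRUE`) and skipped
  by the data/code detectors, which otherwise fire on column headers like
  "GenBank accession". Disclosure detectors still see them, since COI and
  funding footnotes occasionally hide in table notes.

For plain text, a line of at most 60 characters without terminal
punctuation that matches the section-title lexicon is treated as a heading;
paragraph zoning beyond that is delegated to `locate_section()`, which
returns a heading plus the units that follow it up to the next heading.
Footnote and front-matter units never join a titled section — in JATS the
`<fn-group>` that often follows the acknowledgments is structurally
separate, and treating it as part of the acknowledgments would let
ack-localized rules fire on unrelated footnotes. Metadata missing from
plain text stays `NA`; it is never guessed.

## Preprocessing

Normalization is deliberately light because case and punctuation carry
signal here (section titles are capitalised; "Grant no. 12345" depends on
its full stop). `normalize_text()` drops undecodable bytes and control
characters, rejoins words hyphenated across line breaks, and collapses
intra-paragraph line breaks — nothing else. There is no lowercasing, no
stemming, and no stop-word removal.

Tokenization policy is per indicator: data and code sharing are screened
**sentence by sentence** (their signal is local: one availability sentence),
while COI, funding, and registration are screened **paragraph by
paragraph** (their signal is often spread across a disclosure block). The
sentence splitter is a custom rule set with an editable abbreviation guard
(`no.`, `Dr.`, `et al.`, `Fig.`, ...), protection for single-letter
initials ("S.S.") and for stops embedded in tokens ("ClinicalTrials.gov",
"3.5"). Tokens always partition their input, so any match offset maps back
to a verbatim evidence substring.

## Masking, labelling, negation, localization

Detection proceeds in four stages, all driven by the TSV configuration
under `inst/extdata/patterns/` (`load_lexicon()`):

1. **Masking.** Spans that belong to *another* indicator are overwritten
   in place with a placeholder of equal length. The flagship case: "S.S.
   has financial relationships with GSK" is a COI disclosure whose finance
   vocabulary would otherwise read as a funding statement, so it is masked
   before funding labelling. Equal-length replacement keeps all offsets
   valid, which is what makes verbatim evidence extraction safe. The
   shipped mask set covers the finance-in-COI family; additional masks are
   marked "extrapolated" in the config notes and can be edited without
   touching code.
2. **Labelling.** Positive entries fire a lettered category code. The
   taxonomies follow the field's usage: data/code sharing distinguishes
   general databases (a), field databases (b), repositories (c), code
   language (d), file formats (e), supplement language (f), and
   availability-statement language (g); COI has phrase/section/declared/
   none/acknowledgment categories (a)–(e); funding (a)–(h); registration
   (a)–(g) including PROSPERO, registry-agnostic wording, and registration
   identifiers inside funding disclosures. Patterns are written
   bidirectionally so passive and active phrasings both match ("we
   registered the trial" / "the trial was registered").
3. **Negation.** For sentence-level detectors a negation hit vetoes the
   whole sentence ("not deposited", "available upon request", "available
   from the corresponding author"). For paragraph-level detectors the
   negated span is masked instead, so one irrelevant clause ("our hospital
   registry") cannot suppress a genuine statement elsewhere in the same
   paragraph. Request-only availability never counts as sharing: the
   automated definition captures newly generated, openly deposited data
   only, which is narrower than what a human auditor might accept.
4. **Localization.** The most false-positive-prone rules run only inside
   named sections: conflict-associated words like "fees" or "advisory
   board" are only trusted inside the acknowledgments, where they almost
   always are disclosures rather than methods vocabulary.

Database/repository/format mentions additionally require a positive
availability context word in the same sentence ("deposited", "can be
downloaded"); a bare "compared against dbSNP" is a methods mention, not
sharing.

### Subtypes

A COI result is `no_conflict` when only no-conflict wording fired and no
declared-conflict rule did; if both fire the result is conservatively
`conflict_declared`. A funding result is `no_funding` when a no-funding
statement fired and none of the funds-received categories (disclosure
phrase, foundation, thank-you, grant) did. This is slightly broader than
"only the no-funding category fired": the canonical author-referenced
sentence "This author has received no financial support for this research"
fires both the author-referenced and the no-funding category, and calling
it anything but `no_funding` would be wrong.

## Corpus screening and aggregation

`screen_corpus()` flattens each article into one row: five presence flags,
five evidence texts, one boolean per category code, subtype and registry-id
fields, and pass-through metadata. Parsing failures yield a `failed` row
with the reason; a batch never aborts. Output is identical for any worker
count — parallelism is an implementation detail, not a model parameter.
Whether an article is a *research* article is accepted as supplied metadata
(`is_research`); no classifier is implemented, and country is likewise
treated as supplied.

`standardize_labels()` reduces free-text label variants. The rule is: group
variants by shipped alias groups, by punctuation/case-stripped key, and by
whole-token containment of a more frequent label ("Texas, USA" joins
"USA"); within a group, variants occurring at least 20 times map to the
group's most common form, ties broken by byte-order sort so the result is
locale-independent; rarer variants are left alone. The threshold reflects
the judgement that correcting variants seen fewer than 20 times cannot
meaningfully move corpus-level proportions.

`centered_moving_average()` smooths yearly prevalence series. With the
default even window of 4 years the window at year *y* spans *y−2* through
*y+1* — an even window has no symmetric centre, so a convention is
required; this one weights the past slightly more, and it is configurable.
Edge years use the truncated available window.

## Validation statistics

`diagnostic_metrics()` computes sensitivity (recall), specificity, PPV
(precision), NPV, accuracy, the true and estimated prevalence, and the
error (their absolute difference) from a confusion matrix. Ratios with a
zero denominator are `NA`, never 0 — a detector evaluated on all-negative
truth has *undefined*, not zero, sensitivity — and bootstrap iterations
with undefined statistics are skipped and counted rather than coerced.

When a detector flags very few positives, its false-negative rate must be
estimated from a large predicted-negative pool that cannot be read in
full. `weighted_rate()` implements the stratified importance-sampling
estimator: partition the pool into strata by cheap relevance signals,
oversample the informative strata, and reweight,

$$\widehat{T} = \sum_h \frac{N_h}{n_h}\, t_h, \qquad
  \widehat{p} = \widehat{T} \Big/ \sum_h N_h,$$

where stratum *h* has population size \(N_h\), sample size \(n_h\), and
\(t_h\) observed positives. Exhaustively sampled strata contribute exactly;
the standard error uses the usual stratified variance with finite-population
correction (strata with fewer than two sampled units contribute none).

An observed corpus-wide flag rate *p* is corrected for detector error with
the predictive values measured in validation:

$$p_{\text{adj}} = p \cdot \mathrm{PPV} + (1 - p)(1 - \mathrm{NPV}).$$

Applied to the estimated prevalence of any confusion matrix with its own
PPV and NPV, this recovers the true prevalence exactly — an algebraic
identity the test suite checks on a thousand random matrices.

`bootstrap_ci()` is a nonparametric bootstrap (default 5,000 iterations,
2.5/97.5 empirical quantiles taken as order statistics without
interpolation). When the validation design has several sampling stages, the
`strata` argument resamples within each stage independently so every stage
contributes its variability; composing stages hierarchically is left to the
caller, which keeps the function honest about what it resamples.

## The synthetic corpus generator

Real validation requires manually labelled articles, which a package
cannot ship. `generate_corpus()` instead builds JATS articles from a
neutral boilerplate vocabulary plus *planted* statements drawn from a
template bank with three tiers:

* **verbatim** — canonical statements of each category ("This work was
  supported by Grant no. 12345.");
* **paraphrase** — clause reordering and voice changes ("Registration of
  this trial was completed prospectively on ClinicalTrials.gov
  (NCT87654321) before enrolment began.");
* **tricky** — near-miss negatives that must *not* fire ("This study
  enrolled patients in our hospital registry.", "Data are available from
  the corresponding author upon request.").

Plants are placed zone-appropriately (registration in methods, COI in
conflict-typed footnotes, data/code in an availability section,
acknowledgment-tier statements in `<ack>`), and positives also set the
corresponding machine-readable markup so the tag-only baseline
(`xml_tagged_indicators()`) can be scored against the same manifest. One
template deliberately crosses indicators: the COI-finance sentence used to
stress the funding mask is a true COI positive and a true funding negative,
and the manifest records both facts.

Default prevalences (COI 0.8, funding 0.8, data 0.15, code 0.02,
registration 0.05) mirror the rates observed in recent biomedical full-text
samples, so the synthetic corpus exercises the detectors at realistic class
balance — registration and code sharing are rare, disclosures are common.
Tricky negatives are injected among 10% of negatives, a deliberately high
stress rate.

**What passing the closed loop shows — and what it does not.** Perfect
sensitivity and specificity on the verbatim tier shows the engine is sound:
zoning, masking, localization, negation, tokenization, and the lexicons are
mutually consistent, and the bank's tricky negatives are rejected for the
right reasons. It does **not** estimate real-world performance: real
articles phrase statements in unboundedly many ways, bury them in layouts
the generator does not imitate, and contain adversarial text no fixed bank
anticipates. On real corpora the lexicons should be validated against
manual labels with exactly the machinery in this package — stratified
sampling of predicted negatives, diagnostic metrics, bootstrap intervals,
and adjusted prevalence.

## Numerical and design choices

* Percentages are rounded with `round()` only at the reporting edge
  (`indicator_prevalence()`); all stored proportions are unrounded.
* The mask placeholder (`░`) is a character guaranteed absent from every
  lexicon, so masking is idempotent and can never create a match.
* Registry-identifier grammars (NCT + 8 digits, CRD + 8–11 digits, ChiCTR
  alphanumeric, ISRCTN, ACTRN, UMIN, EudraCT) live in configuration.
* Supplement-data language (data category *f*) counts as sharing only in
  positive context, and its category flag is reported separately so
  consumers who consider supplement-only sharing insufficient can exclude
  it downstream.
* Supplement files themselves are not scanned; only the article text is.
* The test suite and acceptance script use desk-scale problem sizes chosen
  as adequate for their purpose: 500-article closed-loop corpora, 1,000
  random confusion matrices and stratified populations, 500 bootstrap
  replications at 5,000 iterations each.

## Limitations

The lexicons are authored from the category descriptions and example
phrasings of the screening literature, not learned from data; their
coverage of rare phrasings is unknown until validated on a manually
labelled sample. English text is assumed. Linked URLs and accession numbers
are not resolved, so a statement can be true and fire correctly while the
data behind it are gone. And the detectors report what articles *say*, not
what their authors did: a complete, accurate, truthful disclosure and a
boilerplate one look the same to a rule.
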