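test_that("COI detection handles declarations, no-conflict wording, and localization", {
  res <- detect_coi(para_article("The authors declare no competing interests.", "footnote"))
  expect_true(res$present)
  expect_true("d" %in% res$categories)
  expect_equal(res$subtype, "no_conflict")

  # acknowledgment-only words fire inside the acknowledgments...
  ack <- para_article("The investigators received honoraria during this period.",
                      "acknowledgments", heading = "Acknowledgments")
  res_ack <- detect_coi(ack)
  expect_true(res_ack$present)
  expect_true("e" %in% res_ack$categories)
  # ...but the same words in the body are not trusted
  body <- para_article("The investigators received honoraria during this period.", "body")
  expect_false("e" %in% detect_coi(body)$categories)

  empty <- new_article("empty")
  res_empty <- detect_coi(empty)
  expect_false(res_empty$present)
  expect_length(res_empty$categories, 0)

  # declared conflict wins over no-conflict wording in the same article
  both <- new_article("both", tibble::tibble(
    text = c("J.J. receives consulting fees from Acme.",
             "All other authors declare no competing interests."),
    zone = "footnote"))
  expect_equal(detect_coi(both)$subtype, "conflict_declared")
})

test_that("funding detection covers grants, no-funding wording, and the COI mask", {
  res <- detect_funding(para_article("This work was supported by Grant no. 12345.", "footnote"))
  expect_true(res$present)
  expect_true("f" %in% res$categories)
  expect_equal(res$subtype, "funds_received")

  res_g <- detect_funding(para_article("No funding was received for this research.", "footnote"))
  expect_true(res_g$present)
  expect_true("g" %in% res_g$categories)
  expect_equal(res_g$subtype, "no_funding")

  # COI finance wording is masked before funding labelling
  coi_text <- para_article("S.S. has financial relationships with GSK", "footnote")
  expect_false(detect_funding(coi_text)$present)
  expect_true(detect_coi(coi_text)$present) # but it is a genuine COI disclosure

  # a heading alone discloses the presence of a funding section
  sec <- para_article("The money paragraph text.", "body", heading = "Funding")
  expect_true("b" %in% detect_funding(sec)$categories)
})

test_that("registration detection extracts identifiers and rejects non-registry mentions", {
  res <- detect_registration(para_article(
    "This study was registered on ClinicalTrials.gov (NCT12345678).", "body"))
  expect_true(res$present)
  expect_true("a" %in% res$categories)
  expect_true("NCT12345678" %in% res$registry_ids)

  res_b <- detect_registration(para_article(
    "This study was registered on PROSPERO (CRD42015023210).", "body"))
  expect_true("b" %in% res_b$categories)
  expect_true("CRD42015023210" %in% res_b$registry_ids)

  # tricky negatives from clinical writing
  expect_false(detect_registration(para_article(
    "This study enrolled patients in our hospital registry.", "body"))$present)
  expect_false(detect_registration(para_article(
    "Our protocol was approved by the IRS (registration no. 123456).", "body"))$present)
})

test_that("data-sharing detection needs positive context and honors negation", {
  expect_true("b" %in% detect_data_sharing(para_article(
    "Sequence data were deposited in dbSNP and can be downloaded.", "body"))$categories)
  expect_false(detect_data_sharing(para_article(
    "Data are available from the corresponding author upon request.", "body"))$present)
  expect_false(detect_data_sharing(para_article(
    "Raw data were not deposited in any repository.", "body"))$present)
  # a database name without availability context is just a mention
  expect_false(detect_data_sharing(para_article(
    "Variants were compared against dbSNP annotations.", "body"))$present)
})

test_that("code-sharing detection accepts repositories and rejects request-only claims", {
  expect_true("c" %in% detect_code_sharing(para_article(
    "All analysis scripts are available at GitHub.", "body"))$categories)
  expect_false(detect_code_sharing(para_article(
    "Code is available upon reasonable request.", "body"))$present)
  expect_false(detect_code_sharing(new_article("empty"))$present)
})

test_that("table and figure captions are excluded from sharing detectors only", {
  units <- tibble::tibble(
    text = "All data were deposited in GenBank and can be downloaded.",
    zone = "body", display = TRUE)
  art <- new_article("cap", units)
  expect_false(detect_data_sharing(art)$present)
  # disclosure detectors still see display units
  art2 <- new_article("cap2", tibble::tibble(
    text = "This work was supported by Grant no. 99.", zone = "body", display = TRUE))
  expect_true(detect_funding(art2)$present)
})

test_that("wrapping a firing statement in negative context suppresses it", {
  pairs <- list(
    c("Sequence data were deposited in dbSNP and can be downloaded.",
      "Sequence data were not deposited in dbSNP."),
    c("All analysis scripts are available at GitHub.",
      "Analysis scripts are available from the corresponding author upon request."),
    c("The dataset is openly available as csv files.",
      "The dataset is available as csv files upon reasonable request.")
  )
  detectors <- list(detect_data_sharing, detect_code_sharing, detect_data_sharing)
  for (i in seq_along(pairs)) {
    expect_true(detectors[[i]](para_article(pairs[[i]][1], "body"))$present)
    expect_false(detectors[[i]](para_article(pairs[[i]][2], "body"))$present)
  }
})

test_that("every bank template is detected (positives) or rejected (tricky negatives)", {
  bank <- template_bank()
  zone_map <- c(methods = "body", back = "footnote", ack = "acknowledgments",
                availability = "back_other", coi_section = "back_other",
                funding_section = "back_other")
  heading_map <- c(coi_section = "Conflicts of Interest",
                   funding_section = "Funding", ack = "Acknowledgments")
  for (i in seq_len(nrow(bank))) {
    r <- bank[i, ]
    heading <- if (r$zone %in% names(heading_map)) heading_map[[r$zone]] else NULL
    art <- para_article(r$text, zone_map[[r$zone]], heading = heading)
    res <- detect_indicator_for_test(art, r$indicator)
    if (r$tier == "tricky") {
      expect_false(res$present, info = r$template_id)
    } else {
      expect_true(res$present, info = r$template_id)
      expect_true(r$category %in% res$categories, info = r$template_id)
    }
  }
})

test_that("evidence strings are substrings of the screened article's units", {
  corpus <- generate_corpus(30, seed = 42)
  for (id in names(corpus$documents)) {
    art <- read_jats(corpus$documents[[id]])
    for (ind in names(pred_col)) {
      res <- detect_indicator_for_test(art, ind)
      for (ev in res$evidence) {
        expect_true(any(vapply(art$units$text, function(u) {
          grepl(ev, u, fixed = TRUE)
        }, logical(1))), info = paste(id, ind))
      }
    }
  }
})

test_that("detector output does not depend on other articles being processed", {
  corpus <- generate_corpus(6, seed = 5)
  alone <- screen_article(corpus$documents[[3]], "jats")
  together <- screen_corpus(corpus$documents, "jats", quiet = TRUE)[3, ]
  expect_identical(alone, together)
})

test_that("extract_evidence returns the containing sentence or the whole unit", {
  unit <- "A first claim sits here. A second claim follows it."
  ev <- extract_evidence(unit, cbind(28, 33), "sentence")
  expect_equal(ev, "A second claim follows it.")
  expect_equal(extract_evidence(unit, cbind(1, nchar(unit)), "paragraph"), unit)
  expect_error(extract_evidence(unit, cbind(10, 999)), "out of range")
})
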