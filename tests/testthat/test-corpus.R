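test_that("screening one article flattens flags, categories, and evidence", {
  g <- generate_article(plant_spec(coi = "coi_d_v1", funding = "fund_f_v1", seed = 2))
  rec <- screen_article(g$xml, "jats")
  expect_equal(unlist(rec[, c("is_data_pred", "is_code_pred", "is_coi_pred",
                              "is_fund_pred", "is_register_pred")], use.names = FALSE),
               c(FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_true(nzchar(rec$coi_text))
  expect_identical(rec$data_text, "")
  expect_true(rec$fund_f)

  # all five planted: all five flags
  g5 <- generate_article(plant_spec(coi = "coi_a_v1", funding = "fund_a_v1",
                                    registration = "reg_a_v1",
                                    data_sharing = "data_a_v1",
                                    code_sharing = "code_c_v1", seed = 3))
  rec5 <- screen_article(g5$xml, "jats")
  expect_true(all(unlist(rec5[, unname(pred_col)])))

  # empty article: all flags false, evidence empty
  rec0 <- screen_article(new_article("none"))
  expect_false(any(unlist(rec0[, unname(pred_col)])))
  expect_identical(unique(unlist(rec0[, c("data_text", "code_text", "coi_text",
                                          "fund_text", "register_text")])), "")
})

test_that("presence flags equal the union of category flags", {
  corpus <- generate_corpus(40, seed = 9)
  recs <- screen_corpus(corpus$documents, "jats", quiet = TRUE)
  prefixes <- c(is_data_pred = "data_", is_code_pred = "code_",
                is_coi_pred = "coi_", is_fund_pred = "fund_",
                is_register_pred = "reg_")
  for (flag in names(prefixes)) {
    cat_cols <- grep(paste0("^", prefixes[[flag]], "[a-h]$"), names(recs), value = TRUE)
    union_flag <- rowSums(as.matrix(recs[, cat_cols])) > 0
    expect_equal(recs[[flag]], unname(union_flag), info = flag)
  }
})

test_that("corpus screening preserves order, tolerates failures, and is worker-invariant", {
  expect_equal(nrow(screen_corpus(character(0), "jats", quiet = TRUE)), 0)
  corpus <- generate_corpus(10, seed = 13)
  serial <- screen_corpus(corpus$documents, "jats", workers = 1, quiet = TRUE)
  parallel4 <- screen_corpus(corpus$documents, "jats", workers = 4, quiet = TRUE)
  expect_identical(serial, parallel4)
  expect_equal(serial$article_id, unname(names(corpus$documents)))

  # one unreadable document: a failed record, not an abort
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<article><oops>", bad)
  docs <- c(corpus$documents[1], bad, corpus$documents[2])
  recs <- screen_corpus(docs, "jats", quiet = TRUE)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$failed, c(FALSE, TRUE, FALSE))
  expect_match(recs$fail_reason[2], "parse")
})

test_that("screened prevalence equals the planted manifest prevalence", {
  corpus <- generate_corpus(100, prevalences = c(coi = 0.2, funding = 0,
                                                 data_sharing = 0,
                                                 code_sharing = 0,
                                                 registration = 0),
                            tricky_negative_rate = 0, seed = 21)
  recs <- screen_corpus(corpus$documents, "jats", quiet = TRUE)
  expect_equal(mean(recs$is_coi_pred), mean(corpus$manifest$coi_truth))
  tab <- prevalence_by(recs)
  expect_equal(tab$coi_prop, mean(corpus$manifest$coi_truth))
})

test_that("label standardization maps frequent variants to the most common form", {
  vals <- c(rep("USA", 50), rep("United States", 30), rep("U.S.A.", 5))
  map <- standardize_labels(vals, min_count = 20)
  expect_equal(unname(map["United States"]), "USA")
  expect_equal(unname(map["U.S.A."]), "U.S.A.") # too rare to standardize
  expect_equal(unname(map["USA"]), "USA")

  # single distinct value: identity
  expect_equal(unname(standardize_labels(rep("Elsevier", 7))), "Elsevier")

  # containment: a rarer longer label joins the frequent contained label
  vals2 <- c(rep("USA", 50), rep("Texas, USA", 20))
  expect_equal(unname(standardize_labels(vals2)["Texas, USA"]), "USA")

  # exact tie: deterministic lexicographic winner, verified by enumeration
  vals3 <- c(rep("Berlin", 20), rep("berlin", 20))
  counts <- table(vals3)
  members <- names(counts)
  expected <- sort(members[counts == max(counts)], method = "radix")[1]
  map3 <- standardize_labels(vals3)
  expect_equal(unname(map3["Berlin"]), expected)
  expect_equal(unname(map3["berlin"]), expected)
})

test_that("proportion arithmetic reproduces printed-style percentages", {
  expect_equal(indicator_prevalence(243783, 2751420)$pct, 8.9)
  expect_equal(indicator_prevalence(218, 246, digits = 0)$pct, 89)
  expect_equal(indicator_prevalence(0, 500)$pct, 0)
  expect_error(indicator_prevalence(5, 0))
})

test_that("prevalence aggregation counts and proportions are consistent", {
  recs <- dplyr::bind_rows(
    tibble::tibble(article_id = as.character(1:6), journal = "A",
                   is_data_pred = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   is_code_pred = FALSE, is_coi_pred = TRUE,
                   is_fund_pred = FALSE, is_register_pred = FALSE),
    tibble::tibble(article_id = as.character(7:9), journal = c("B", "B", NA),
                   is_data_pred = FALSE, is_code_pred = FALSE,
                   is_coi_pred = c(TRUE, FALSE, TRUE),
                   is_fund_pred = FALSE, is_register_pred = FALSE))
  tab <- prevalence_by(recs, "journal", min_group = 5)
  expect_equal(sum(tab$n_total), sum(!is.na(recs$journal)))
  a <- tab[tab$journal == "A", ]
  expect_equal(a$data_prop, 2 / 6)
  expect_equal(a$below_min, FALSE)
  b <- tab[tab$journal == "B", ]
  expect_equal(b$coi_prop, 0.5)
  expect_true(b$below_min)
})

test_that("centered moving average uses the stated window convention", {
  const <- setNames(rep(0.5, 6), 2001:2006)
  expect_equal(centered_moving_average(const, 4), const)
  series <- c(`1` = 0, `2` = 0, `3` = 1, `4` = 1)
  out <- centered_moving_average(series, 4)
  expect_equal(unname(out["3"]), 0.5) # window covers all four years
  expect_equal(unname(out["1"]), 0)   # truncated edge window
  single <- c(`2020` = 0.3)
  expect_equal(centered_moving_average(single, 4), single)
  expect_error(centered_moving_average(series, 0), "window")
})
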