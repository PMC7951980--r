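# shared fixture builders: every fixture is constructed in code at test time

# a one-paragraph article with the text in a chosen zone
para_article <- function(text, zone = "body", heading = NULL) {
  units <- tibble::tibble(text = text, zone = zone)
  if (!is.null(heading)) {
    units <- dplyr::bind_rows(tibble::tibble(text = heading, zone = "heading"),
                              units)
  }
  new_article("test-article", units)
}

# minimal JATS document with configurable parts
jats_doc <- function(journal = "Test Journal", body = "", back = "",
                     meta_extra = "") {
  sprintf('<?xml version="1.0"?>
<article article-type="research-article">
<front>
<journal-meta><journal-title-group><journal-title>%s</journal-title></journal-title-group></journal-meta>
<article-meta>
<article-id pub-id-type="pmcid">PMC0001</article-id>
<title-group><article-title>A fixture article</article-title></title-group>
<pub-date><year>2018</year></pub-date>
%s
</article-meta>
</front>
<body>%s</body>
<back>%s</back>
</article>', journal, meta_extra, body, back)
}

detect_indicator_for_test <- function(article, indicator) {
  switch(indicator,
         coi = detect_coi(article),
         funding = detect_funding(article),
         registration = detect_registration(article),
         data_sharing = detect_data_sharing(article),
         code_sharing = detect_code_sharing(article))
}

pred_col <- c(data_sharing = "is_data_pred", code_sharing = "is_code_pred",
              coi = "is_coi_pred", funding = "is_fund_pred",
              registration = "is_register_pred")
truth_col <- c(data_sharing = "data_truth", code_sharing = "code_truth",
               coi = "coi_truth", funding = "fund_truth",
               registration = "reg_truth")
tier_col <- c(data_sharing = "data_tier", code_sharing = "code_tier",
              coi = "coi_tier", funding = "fund_tier",
              registration = "reg_tier")
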