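# Synthetic JATS articles with planted indicator statements and truth
# manifests. The template bank is the detectors' specification surface:
# "verbatim" templates are canonical indicator statements, "paraphrase"
# templates reorder clauses or switch voice, and "tricky" templates are
# near-miss negatives ("hospital registry", "upon request") that a correct
# detector must reject.

# filler drawn from a fixed neutral vocabulary so boilerplate never brushes
# against the lexicons (verified by the all-absent corpus test)
FILLER_SENTENCES <- c(
  "Cultures were maintained at a constant temperature throughout the observation period.",
  "The primary outcome was assessed at twelve weeks by blinded observers.",
  "Participants completed the questionnaire during a routine clinic visit.",
  "Tissue sections were stained and examined under light microscopy.",
  "The intervention group showed a modest change relative to baseline.",
  "Samples were processed within two hours of collection.",
  "Statistical analyses were performed with standard methods described previously.",
  "The secondary endpoints are summarised in the main text.",
  "Measurements were repeated three times and averaged.",
  "Enrolment took place across four clinical sites over two years.",
  "The cohort comprised adults aged between forty and sixty years.",
  "Imaging was carried out on the day following admission."
)
FILLER_TITLES <- c(
  "A prospective evaluation of outcome measures in a clinical cohort",
  "Observational findings from a multicentre sample of adult participants",
  "Longitudinal assessment of a routine intervention in practice"
)
FILLER_JOURNALS <- c("Journal of Synthetic Biomedicine",
                     "Annals of Synthetic Medicine",
                     "Synthetic Clinical Reports")

#' The planted-statement template bank
#'
#' @param lexicon Unused placeholder for API symmetry.
#' @return A tibble with columns `template_id`, `indicator`, `category`,
#'   `tier` (`verbatim`, `paraphrase`, `tricky`), `zone`, `also_sets`, and
#'   `text`.
#' @export
template_bank <- function(lexicon = NULL) {
  if (is.null(the$templates)) {
    path <- system.file("extdata", "templates", "template_bank.tsv",
                        package = "transcreen")
    the$templates <- tibble::as_tibble(
      utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                        encoding = "UTF-8"))
  }
  the$templates
}

#' Specify what to plant in one synthetic article
#'
#' Exactly one directive per indicator: `"absent"`, or a `template_id` from
#' [template_bank()] (positive or tricky-negative tiers).
#'
#' @param article_id Identifier for the generated article.
#' @param coi,funding,registration,data_sharing,code_sharing Directives.
#' @param year,journal Metadata overrides (`NULL` = drawn from fixed lists).
#' @param seed Integer seed controlling boilerplate and metadata draws.
#' @return A list of class `transcreen_plant_spec`.
#' @export
plant_spec <- function(article_id = "synthetic-0001", coi = "absent",
                       funding = "absent", registration = "absent",
                       data_sharing = "absent", code_sharing = "absent",
                       year = NULL, journal = NULL, seed = 1L) {
  bank <- template_bank()
  directives <- list(coi = coi, funding = funding, registration = registration,
                     data_sharing = data_sharing, code_sharing = code_sharing)
  for (ind in names(directives)) {
    d <- directives[[ind]]
    stopifnot(is.character(d), length(d) == 1)
    if (d == "absent") next
    row <- bank[bank$template_id == d, ]
    if (nrow(row) == 0) stop("unknown template id: ", d)
    if (row$indicator != ind) {
      stop("template ", d, " belongs to indicator ", row$indicator, ", not ", ind)
    }
  }
  out <- list(article_id = article_id, directives = directives, year = year,
              journal = journal, seed = as.integer(seed))
  class(out) <- "transcreen_plant_spec"
  out
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Generate one synthetic JATS article
#'
#' Builds a well-formed JATS document with neutral boilerplate plus the
#' planted statements in zone-appropriate positions: conflict/funding
#' statements in back-matter footnotes or titled sections, registration in
#' the methods section, data/code statements in an availability section,
#' acknowledgment-tier statements inside `<ack>`. Planted positives also set
#' the corresponding machine-readable markup (conflict-typed footnote,
#' funding-group, data-availability section) so the tag-only baseline can be
#' scored against the same manifest. Same spec, same output, byte for byte.
#'
#' @param spec A [plant_spec()].
#' @return A list with `xml` (a single string) and `manifest` (a one-row
#'   tibble of truth flags, planted categories, tiers, evidence strings and
#'   tagged-markup flags).
#' @export
generate_article <- function(spec) {
  stopifnot(inherits(spec, "transcreen_plant_spec"))
  bank <- template_bank()
  withr::with_seed(spec$seed, {
    year <- if (is.null(spec$year)) sample(2015:2019, 1) else as.integer(spec$year)
    journal <- if (is.null(spec$journal)) sample(FILLER_JOURNALS, 1) else spec$journal
    title <- sample(FILLER_TITLES, 1)
    para <- function(k = 2) paste(sample(FILLER_SENTENCES, k), collapse = " ")
    fillers <- replicate(6, para(), simplify = TRUE)
  })

  plants <- list()
  manifest <- tibble::tibble(article_id = spec$article_id, year = year,
                             journal = journal)
  tagged <- list(coi = FALSE, funding = FALSE, data = FALSE)
  for (ind in names(spec$directives)) {
    d <- spec$directives[[ind]]
    pfx <- IND_PREFIX[[ind]]
    truth <- FALSE; template <- NA_character_; tier <- NA_character_
    category <- NA_character_; evidence <- NA_character_; zone <- NA_character_
    if (d != "absent") {
      row <- bank[bank$template_id == d, ]
      template <- row$template_id; tier <- row$tier; zone <- row$zone
      evidence <- row$text
      truth <- row$tier != "tricky"
      category <- if (truth) row$category else NA_character_
      plants[[length(plants) + 1L]] <- row
      if (truth && ind == "coi") tagged$coi <- TRUE
      if (truth && ind == "funding") tagged$funding <- TRUE
      if (truth && ind == "data_sharing") tagged$data <- TRUE
    }
    manifest[[paste0(pfx, "_truth")]] <- truth
    manifest[[paste0(pfx, "_template")]] <- template
    manifest[[paste0(pfx, "_tier")]] <- tier
    manifest[[paste0(pfx, "_category")]] <- category
    manifest[[paste0(pfx, "_evidence")]] <- evidence
    manifest[[paste0(pfx, "_zone")]] <- zone
  }
  plants <- if (length(plants) > 0) dplyr::bind_rows(plants) else bank[0, ]

  # a tricky template can genuinely instantiate another indicator
  # (e.g. the COI-finance sentence used to stress the funding mask)
  for (i in seq_len(nrow(plants))) {
    als <- plants$also_sets[i]
    if (is.na(als) || !nzchar(als)) next
    parts <- strsplit(als, ":", fixed = TRUE)[[1]]
    pfx <- IND_PREFIX[[parts[1]]]
    if (!manifest[[paste0(pfx, "_truth")]]) {
      manifest[[paste0(pfx, "_truth")]] <- TRUE
      manifest[[paste0(pfx, "_template")]] <- plants$template_id[i]
      manifest[[paste0(pfx, "_tier")]] <- "verbatim"
      manifest[[paste0(pfx, "_category")]] <- parts[2]
      manifest[[paste0(pfx, "_evidence")]] <- plants$text[i]
      manifest[[paste0(pfx, "_zone")]] <- plants$zone[i]
      if (parts[1] == "coi") tagged$coi <- TRUE
    }
  }

  zone_texts <- function(z) xml_escape(plants$text[plants$zone == z])
  p_tags <- function(txts) paste(sprintf("<p>%s</p>", txts), collapse = "\n")

  methods_extra <- p_tags(zone_texts("methods"))
  ack_extra <- p_tags(zone_texts("ack"))
  avail_txt <- zone_texts("availability")
  coi_sec_txt <- zone_texts("coi_section")
  fund_sec_txt <- zone_texts("funding_section")
  back_txt <- zone_texts("back")

  back_fns <- character(0)
  for (txt in back_txt) {
    src <- plants[plants$zone == "back", ]
    ind_of <- src$indicator[xml_escape(src$text) == txt][1]
    fn_type <- if (identical(ind_of, "coi")) " fn-type=\"conflict\"" else ""
    back_fns <- c(back_fns, sprintf("<fn%s><p>%s</p></fn>", fn_type, txt))
  }
  fn_group <- if (length(back_fns) > 0) {
    sprintf("<fn-group>%s</fn-group>", paste(back_fns, collapse = "\n"))
  } else ""
  avail_sec <- if (length(avail_txt) > 0) {
    sprintf("<sec sec-type=\"data-availability\"><title>Data Availability</title>%s</sec>",
            p_tags(avail_txt))
  } else ""
  coi_sec <- if (length(coi_sec_txt) > 0) {
    sprintf("<sec><title>Conflicts of Interest</title>%s</sec>", p_tags(coi_sec_txt))
  } else ""
  fund_sec <- if (length(fund_sec_txt) > 0) {
    sprintf("<sec><title>Funding</title>%s</sec>", p_tags(fund_sec_txt))
  } else ""
  funding_group <- if (tagged$funding) {
    "<funding-group><award-group><funding-source>Synthetic Funder</funding-source></award-group></funding-group>"
  } else ""

  xml <- sprintf(
'<?xml version="1.0" encoding="UTF-8"?>
<article article-type="research-article">
<front>
<journal-meta>
<journal-title-group><journal-title>%s</journal-title></journal-title-group>
<publisher><publisher-name>Synthetic Press</publisher-name></publisher>
</journal-meta>
<article-meta>
<article-id pub-id-type="pmcid">%s</article-id>
<title-group><article-title>%s</article-title></title-group>
<pub-date><year>%d</year></pub-date>
%s
<abstract><p>%s</p></abstract>
</article-meta>
</front>
<body>
<sec><title>Introduction</title><p>%s</p></sec>
<sec sec-type="methods"><title>Methods</title><p>%s</p>
%s</sec>
<sec><title>Results</title><p>%s</p>
<table-wrap><caption><p>%s</p></caption></table-wrap></sec>
</body>
<back>
<ack><title>Acknowledgments</title><p>We thank the nursing staff for their assistance with sample collection.</p>
%s</ack>
%s
%s
%s
%s
<ref-list><title>References</title>
<ref id="r1"><mixed-citation>Reference entry one, nineteen eighty nine.</mixed-citation></ref>
<ref id="r2"><mixed-citation>Reference entry two, nineteen ninety five.</mixed-citation></ref>
</ref-list>
</back>
</article>',
    xml_escape(journal), xml_escape(spec$article_id), xml_escape(title), year,
    funding_group, xml_escape(fillers[1]), xml_escape(fillers[2]),
    xml_escape(fillers[3]), methods_extra, xml_escape(fillers[4]),
    xml_escape(fillers[5]), ack_extra, avail_sec, coi_sec, fund_sec, fn_group)

  manifest$coi_tagged <- tagged$coi
  manifest$funding_tagged <- tagged$funding
  manifest$data_tagged <- tagged$data
  list(xml = xml, manifest = manifest)
}

#' Generate a synthetic corpus with known indicator prevalences
#'
#' Indicator plants are drawn independently per article at the stated
#' prevalences; among articles negative for an indicator, a tricky-negative
#' statement is injected at `tricky_negative_rate`. The returned manifest
#' records exactly what was planted, so screening results can be scored
#' against ground truth.
#'
#' @param n Number of articles.
#' @param prevalences Named fractions per indicator (defaults mirror a
#'   recent biomedical full-text sample: COI 0.8, funding 0.8, data 0.15,
#'   code 0.02, registration 0.05).
#' @param tricky_negative_rate Fraction of indicator-negative articles that
#'   carry a near-miss negative statement.
#' @param seed Integer seed; the corpus is reproducible byte for byte.
#' @param tiers Template tiers positives are drawn from.
#' @param outdir Optional directory; when given, one `.xml` file per article
#'   plus a `manifest.tsv` are written there.
#' @return A list with `documents` (named character vector of JATS XML) and
#'   `manifest` (tibble, one row per article).
#' @export
generate_corpus <- function(n, prevalences = c(coi = 0.8, funding = 0.8,
                                               data_sharing = 0.15,
                                               code_sharing = 0.02,
                                               registration = 0.05),
                            tricky_negative_rate = 0.1, seed = 1L,
                            tiers = c("verbatim", "paraphrase"),
                            outdir = NULL) {
  stopifnot(n >= 0, all(prevalences >= 0), all(prevalences <= 1),
            tricky_negative_rate >= 0, tricky_negative_rate <= 1)
  missing_ind <- setdiff(INDICATORS, names(prevalences))
  if (length(missing_ind) > 0) {
    prevalences[missing_ind] <- 0
  }
  bank <- template_bank()
  if (n == 0) {
    return(list(documents = character(0), manifest = tibble::tibble()))
  }

  specs <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i) {
      directives <- list()
      for (ind in INDICATORS) {
        pos <- runif(1) < prevalences[[ind]]
        if (pos) {
          pool <- bank$template_id[bank$indicator == ind & bank$tier %in% tiers]
          directives[[ind]] <- sample(pool, 1)
        } else if (runif(1) < tricky_negative_rate) {
          pool <- bank$template_id[bank$indicator == ind & bank$tier == "tricky"]
          directives[[ind]] <- if (length(pool) > 0) sample(pool, 1) else "absent"
        } else {
          directives[[ind]] <- "absent"
        }
      }
      plant_spec(article_id = sprintf("synthetic-%04d", i),
                 coi = directives$coi, funding = directives$funding,
                 registration = directives$registration,
                 data_sharing = directives$data_sharing,
                 code_sharing = directives$code_sharing,
                 seed = (as.integer(seed) + i * 131L) %% .Machine$integer.max)
    })
  })

  arts <- lapply(specs, generate_article)
  documents <- vapply(arts, function(a) a$xml, character(1))
  names(documents) <- vapply(specs, function(s) s$article_id, character(1))
  manifest <- dplyr::bind_rows(lapply(arts, function(a) a$manifest))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(documents)) {
      writeLines(documents[[id]], file.path(outdir, paste0(id, ".xml")),
                 useBytes = TRUE)
    }
    utils::write.table(manifest, file.path(outdir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(documents = documents, manifest = manifest)
}
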