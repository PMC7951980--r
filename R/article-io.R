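# Reading JATS/NLM XML and plain text into a zone-labelled document model.

ZONES <- c("title", "abstract", "body", "heading", "acknowledgments",
           "footnote", "back_other")

#' Construct an article
#'
#' An article is the uniform document model screened by the detectors: a
#' small set of metadata fields plus an ordered collection of text units,
#' each labelled with the zone it came from (`title`, `abstract`, `body`,
#' `heading`, `acknowledgments`, `footnote`, `back_other`) and a flag for
#' display material (table/figure captions). Reference-list content is never
#' admitted as a unit, so it can never be matched. Unit text is normalized at
#' construction.
#'
#' @param article_id Non-empty identifier string.
#' @param units A data frame with columns `text` and `zone` (optionally
#'   `display`); empty units are dropped, order is preserved.
#' @param pmid,pmcid,journal,publisher,year,article_type Optional metadata;
#'   left `NA` when unknown, never guessed.
#' @return An object of class `transcreen_article`.
#' @export
new_article <- function(article_id, units = NULL, pmid = NA_character_,
                        pmcid = NA_character_, journal = NA_character_,
                        publisher = NA_character_, year = NA_integer_,
                        article_type = NA_character_) {
  stopifnot(is.character(article_id), length(article_id) == 1, nzchar(article_id))
  if (is.null(units)) {
    units <- tibble::tibble(text = character(0), zone = character(0),
                            display = logical(0))
  }
  units <- tibble::as_tibble(units)
  if (!"display" %in% names(units)) units$display <- FALSE
  units$text <- normalize_text(units$text)
  units <- units[nzchar(units$text), c("text", "zone", "display")]
  stopifnot(all(units$zone %in% ZONES))
  units$index <- seq_len(nrow(units)) - 1L
  out <- list(article_id = article_id, pmid = pmid, pmcid = pmcid,
              journal = journal, publisher = publisher,
              year = if (is.na(year)) NA_integer_ else as.integer(year),
              article_type = article_type, units = units)
  class(out) <- "transcreen_article"
  out
}

#' @export
print.transcreen_article <- function(x, ...) {
  cat(sprintf("<transcreen_article> %s (%s, %s)\n", x$article_id,
              ifelse(is.na(x$journal), "journal unknown", x$journal),
              ifelse(is.na(x$year), "year unknown", x$year)))
  if (nrow(x$units) == 0) {
    cat("  0 units\n")
  } else {
    tab <- table(factor(x$units$zone, levels = ZONES))
    tab <- tab[tab > 0]
    cat(sprintf("  %d units: %s\n", nrow(x$units),
                paste(names(tab), unname(tab), sep = "=", collapse = ", ")))
  }
  invisible(x)
}

xml_text1 <- function(doc, xpath) {
  node <- xml2::xml_find_first(doc, xpath)
  if (inherits(node, "xml_missing")) NA_character_ else stringr::str_squish(xml2::xml_text(node))
}

#' Read a JATS/NLM XML article
#'
#' Parses an article from the PMC open-access archival tag set into the
#' zone-labelled document model. Front matter contributes title and abstract
#' units and the metadata fields; the body contributes headings, paragraphs,
#' and display captions (captions are flagged so sharing detectors can skip
#' them); back matter contributes acknowledgments, footnotes, and other back
#' sections. The reference list is excluded by construction. Unknown elements
#' are descended into and their text kept.
#'
#' @param xml_document Path to a JATS XML file, or a string of XML content.
#' @param article_id Identifier to use when none can be derived from the
#'   document.
#' @return A [new_article()] object.
#' @examples
#' art <- read_jats('<article><front><article-meta>
#'   <title-group><article-title>A study</article-title></title-group>
#'   </article-meta></front><body><p>A body paragraph.</p></body></article>')
#' art$units
#' @export
read_jats <- function(xml_document, article_id = NULL) {
  doc <- tryCatch(
    xml2::read_xml(xml_document),
    error = function(e) {
      label <- if (is.character(xml_document) && length(xml_document) == 1 &&
                   !grepl("<", xml_document, fixed = TRUE)) {
        xml_document
      } else "<inline XML>"
      stop("failed to parse JATS XML from ", label, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )

  pmid <- xml_text1(doc, ".//article-meta/article-id[@pub-id-type='pmid']")
  pmcid <- xml_text1(doc, ".//article-meta/article-id[@pub-id-type='pmcid' or @pub-id-type='pmc']")
  journal <- xml_text1(doc, ".//journal-meta//journal-title")
  publisher <- xml_text1(doc, ".//journal-meta//publisher-name")
  year_txt <- xml_text1(doc, ".//article-meta/pub-date/year")
  year <- suppressWarnings(as.integer(year_txt))
  article_type <- xml2::xml_attr(xml2::xml_find_first(doc, "/article"), "article-type")
  if (is.null(article_id)) {
    article_id <- if (!is.na(pmcid)) pmcid else if (!is.na(pmid)) pmid else
      xml_text1(doc, ".//article-meta/article-id")
    if (is.na(article_id) || !nzchar(article_id)) article_id <- "unidentified-article"
  }

  units <- list()
  add <- function(text, zone, display = FALSE) {
    units[[length(units) + 1L]] <<- list(text = text, zone = zone, display = display)
  }

  title <- xml_text1(doc, ".//article-meta//article-title")
  if (!is.na(title) && nzchar(title)) add(title, "title")
  for (p in xml2::xml_find_all(doc, ".//article-meta/abstract//p")) {
    add(xml2::xml_text(p), "abstract")
  }

  # body: walk headings, paragraphs and captions in document order;
  # reference lists and nested captions are handled by the XPaths
  body <- xml2::xml_find_first(doc, "/article/body")
  if (!inherits(body, "xml_missing")) {
    nodes <- xml2::xml_find_all(
      body,
      ".//sec/title | .//p[not(ancestor::table-wrap) and not(ancestor::fig) and not(ancestor::ref-list)] | .//table-wrap//caption//p | .//fig//caption//p"
    )
    for (nd in nodes) {
      anc <- xml2::xml_find_first(nd, "ancestor::table-wrap | ancestor::fig")
      in_display <- !inherits(anc, "xml_missing")
      zone <- if (xml2::xml_name(nd) == "title") "heading" else "body"
      add(xml2::xml_text(nd), zone, display = in_display && zone == "body")
    }
  }

  back <- xml2::xml_find_first(doc, "/article/back")
  if (!inherits(back, "xml_missing")) {
    for (nd in xml2::xml_find_all(back, "./ack")) {
      t <- xml2::xml_find_first(nd, "./title")
      if (!inherits(t, "xml_missing")) add(xml2::xml_text(t), "heading")
      for (p in xml2::xml_find_all(nd, ".//p")) add(xml2::xml_text(p), "acknowledgments")
    }
    for (nd in xml2::xml_find_all(back, ".//fn-group//fn | ./notes//fn | .//author-notes/fn")) {
      add(xml2::xml_text(nd), "footnote")
    }
    for (nd in xml2::xml_find_all(back, "./sec")) {
      t <- xml2::xml_find_first(nd, "./title")
      if (!inherits(t, "xml_missing")) add(xml2::xml_text(t), "heading")
      for (p in xml2::xml_find_all(nd, ".//p[not(ancestor::ref-list)]")) {
        add(xml2::xml_text(p), "back_other")
      }
    }
    for (nd in xml2::xml_find_all(back, "./notes/p")) add(xml2::xml_text(nd), "back_other")
  }
  # conflict/funding statements can also live in front-matter author notes
  for (nd in xml2::xml_find_all(doc, ".//article-meta/author-notes/fn")) {
    add(xml2::xml_text(nd), "footnote")
  }
  for (nd in xml2::xml_find_all(doc, ".//article-meta//funding-statement")) {
    add(xml2::xml_text(nd), "footnote")
  }

  units <- dplyr::bind_rows(lapply(units, tibble::as_tibble))
  new_article(article_id, units, pmid = pmid, pmcid = pmcid, journal = journal,
              publisher = publisher, year = year, article_type = article_type)
}

#' Read a plain-text article
#'
#' Accepts text as produced by PDF-to-text conversion. A trailing
#' reference list (a "References"-style heading through end of file) is
#' removed, paragraphs are split on blank lines, and short unpunctuated
#' lines matching the section-title lexicon are labelled as headings. All
#' other units are body text; zone refinement (e.g. which paragraphs are the
#' acknowledgments) is the job of [locate_section()]. Metadata absent from
#' plain text stays `NA`.
#'
#' @param text A single string (may contain newlines), or a path to a text
#'   file.
#' @param article_id Identifier for the article.
#' @param lexicon A lexicon (for the section-title patterns).
#' @return A [new_article()] object.
#' @export
read_plaintext <- function(text, article_id, lexicon = default_lexicon()) {
  stopifnot(is.character(text), length(text) == 1)
  if (file.exists(text) && !grepl("\n", text, fixed = TRUE)) {
    text <- paste(readLines(text, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }
  text <- iconv(enc2utf8(text), from = "UTF-8", to = "UTF-8", sub = "")
  text <- strip_reference_tail(text)
  paras <- strsplit(text, "\n[ \t]*\n+")[[1]]
  paras <- paras[grepl("\\S", paras)]
  if (length(paras) == 0) return(new_article(article_id))

  is_heading <- vapply(paras, function(p) {
    line <- stringr::str_squish(p)
    if (nchar(line) > 60 || grepl("[.!?;,]$", line)) return(FALSE)
    any(vapply(seq_len(nrow(lexicon$section_titles)), function(i) {
      stringr::str_detect(line, lex_regex(lexicon$section_titles$pattern[i],
                                          lexicon$section_titles$ignore_case[i]))
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)

  units <- tibble::tibble(text = paras,
                          zone = ifelse(is_heading, "heading", "body"))
  new_article(article_id, units)
}

#' Locate a named section of an article
#'
#' Returns the units belonging to a section recognised by the section-title
#' lexicon: a heading matching the requested kind plus all following units up
#' to the next heading. For JATS articles, zones assigned at parse time also
#' count (e.g. `<ack>` paragraphs for `kind = "acknowledgments"`).
#'
#' @param article A [new_article()] object.
#' @param kind One of `"acknowledgments"`, `"coi_statement"`,
#'   `"funding_statement"`, `"methods"`.
#' @param lexicon A lexicon.
#' @return A tibble of units (possibly empty).
#' @export
locate_section <- function(article, kind = c("acknowledgments", "coi_statement",
                                             "funding_statement", "methods"),
                           lexicon = default_lexicon()) {
  kind <- match.arg(kind)
  units <- article$units
  if (nrow(units) == 0) return(units)
  titles <- lexicon$section_titles[lexicon$section_titles$kind == kind, ]
  match_title <- function(txt) {
    any(vapply(seq_len(nrow(titles)), function(i) {
      stringr::str_detect(txt, lex_regex(titles$pattern[i], titles$ignore_case[i]))
    }, logical(1)))
  }
  keep <- rep(FALSE, nrow(units))
  if (kind == "acknowledgments") keep <- keep | units$zone == "acknowledgments"
  in_section <- FALSE
  for (i in seq_len(nrow(units))) {
    if (units$zone[i] == "heading") {
      in_section <- match_title(units$text[i])
      keep[i] <- keep[i] | in_section
    } else if (units$zone[i] %in% c("body", "back_other", "acknowledgments")) {
      keep[i] <- keep[i] | in_section
    } else {
      # footnotes and front matter are not part of a titled section
      in_section <- FALSE
    }
  }
  units[keep, , drop = FALSE]
}

#' Detect indicator statements from XML markup alone
#'
#' Checks only the machine-readable markup of a JATS document — conflict-typed
#' footnotes, `<funding-group>` elements, data-availability-typed sections —
#' and ignores all free text. This is the tag-only baseline: what a consumer
#' of the archive's structured metadata would see without any text mining.
#' The tag set examined is configuration (`xml_tags.tsv`), not code.
#'
#' @param xml_document Path to a JATS XML file, or a string of XML content.
#' @param lexicon A lexicon (for the tag XPaths).
#' @return A list with logical elements `coi_tagged`, `funding_tagged`,
#'   `data_tagged`.
#' @export
xml_tagged_indicators <- function(xml_document, lexicon = default_lexicon()) {
  doc <- tryCatch(xml2::read_xml(xml_document), error = function(e) {
    stop("failed to parse JATS XML: ", conditionMessage(e), call. = FALSE)
  })
  tags <- lexicon$xml_tags
  flag <- function(name) {
    xp <- tags$xpath[tags$flag == name]
    any(vapply(xp, function(x) length(xml2::xml_find_all(doc, x)) > 0, logical(1)))
  }
  list(coi_tagged = flag("coi_tagged"),
       funding_tagged = flag("funding_tagged"),
       data_tagged = flag("data_tagged"))
}
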