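# The five rule-based indicator detectors.
#
# Each detector runs labelling patterns over the article's text units under
# its tokenization policy (sentences for data/code sharing, paragraphs for
# the disclosure indicators), after masking text that belongs to another
# indicator and after cancelling spans recognised by negation rules.
# Sensitive rules are localized: they only run inside named sections (e.g.
# acknowledgment-only conflict words) to reduce mislabelling.

new_indicator_result <- function(indicator, categories = character(0),
                                 evidence = character(0),
                                 subtype = NA_character_,
                                 registry_ids = character(0)) {
  out <- list(indicator = indicator,
              present = length(categories) > 0,
              categories = sort(unique(categories)),
              evidence = unique(evidence),
              subtype = subtype,
              registry_ids = unique(registry_ids))
  class(out) <- "transcreen_indicator_result"
  out
}

#' @export
print.transcreen_indicator_result <- function(x, ...) {
  cat(sprintf("<%s> present: %s", x$indicator, x$present))
  if (x$present) {
    cat(sprintf("  [categories: %s]", paste(x$categories, collapse = ",")))
    if (!is.na(x$subtype)) cat(sprintf("  subtype: %s", x$subtype))
  }
  cat("\n")
  if (length(x$registry_ids) > 0) {
    cat("  registry ids:", paste(x$registry_ids, collapse = ", "), "\n")
  }
  for (e in x$evidence) cat("  evidence:", substr(e, 1, 120), "\n")
  invisible(x)
}

# unit indices (0-based, matching article$units$index) inside acknowledgments
ack_unit_index <- function(article, lexicon) {
  locate_section(article, "acknowledgments", lexicon)$index
}

detect_indicator_ <- function(article, indicator, lexicon = default_lexicon()) {
  stopifnot(inherits(article, "transcreen_article"))
  policy <- tokenization_policy(indicator)
  units <- article$units
  # sharing detectors skip table and figure captions
  if (policy == "sentence") units <- units[!units$display, , drop = FALSE]

  entries <- lexicon$patterns[lexicon$patterns$indicator == indicator, , drop = FALSE]
  pos <- entries[entries$polarity == "positive", , drop = FALSE]
  ctx <- entries[entries$polarity == "context", , drop = FALSE]
  neg <- entries[entries$polarity == "negation", , drop = FALSE]
  ack_idx <- ack_unit_index(article, lexicon)

  # collect every searchable segment first, then match each pattern
  # vectorized across all segments
  seg_masked <- character(0); seg_orig <- character(0)
  seg_ack <- logical(0); seg_heading <- logical(0)
  for (u in seq_len(nrow(units))) {
    raw <- units$text[u]
    masked <- apply_masks(raw, indicator, lexicon)
    if (policy == "paragraph" && nrow(neg) > 0) {
      # negation masks the offending span; the rest of the paragraph stays live
      for (i in seq_len(nrow(neg))) {
        spans <- stringr::str_locate_all(
          masked, lex_regex(neg$pattern[i], neg$ignore_case[i]))[[1]]
        masked <- mask_spans(masked, spans)
      }
    }
    segs <- tokenize_text(masked, policy, lexicon)
    if (nrow(segs) == 0) next
    seg_masked <- c(seg_masked, segs$text)
    seg_orig <- c(seg_orig, substr(rep(raw, nrow(segs)), segs$start, segs$end))
    seg_ack <- c(seg_ack, rep(units$index[u] %in% ack_idx, nrow(segs)))
    seg_heading <- c(seg_heading, rep(units$zone[u] == "heading", nrow(segs)))
  }

  categories <- character(0)
  evidence <- character(0)
  fired_segments <- character(0)

  if (length(seg_masked) > 0) {
    detect_all <- function(rows) {
      hit <- rep(FALSE, length(seg_masked))
      for (i in seq_len(nrow(rows))) {
        hit <- hit | stringr::str_detect(
          seg_masked, lex_regex(rows$pattern[i], rows$ignore_case[i]))
      }
      hit
    }
    # sentence-level negation vetoes the whole sentence
    negated <- if (policy == "sentence" && nrow(neg) > 0) detect_all(neg) else
      rep(FALSE, length(seg_masked))
    ctx_ok <- if (nrow(ctx) > 0) detect_all(ctx) else rep(TRUE, length(seg_masked))

    for (i in seq_len(nrow(pos))) {
      zone_ok <- switch(pos$zone[i], all = rep(TRUE, length(seg_masked)),
                        ack = seg_ack, heading = seg_heading)
      fired <- zone_ok & !negated &
        stringr::str_detect(seg_masked, lex_regex(pos$pattern[i], pos$ignore_case[i]))
      if (pos$needs_context[i] == 1) fired <- fired & ctx_ok
      if (any(fired)) {
        categories <- c(categories, pos$code[i])
        evidence <- c(evidence, seg_orig[fired])
        fired_segments <- c(fired_segments, seg_orig[fired])
      }
    }
  }

  registry_ids <- character(0)
  if (indicator == "registration" && length(fired_segments) > 0) {
    for (i in seq_len(nrow(lexicon$registry_ids))) {
      hits <- stringr::str_extract_all(fired_segments, lexicon$registry_ids$pattern[i])
      registry_ids <- c(registry_ids, unlist(hits))
    }
  }

  subtype <- NA_character_
  cats <- unique(categories)
  if (length(cats) > 0 && indicator == "coi") {
    subtype <- if ("d" %in% cats && !any(c("c", "e") %in% cats)) "no_conflict" else "conflict_declared"
  }
  if (length(cats) > 0 && indicator == "funding") {
    subtype <- if ("g" %in% cats && !any(c("a", "c", "e", "f") %in% cats)) "no_funding" else "funds_received"
  }

  new_indicator_result(indicator, categories, evidence, subtype, registry_ids)
}

#' Detect a conflict-of-interest disclosure
#'
#' Paragraph-level rules fire on (a) phrases associated with a disclosure
#' ("conflicts of interest", "competing interests"), (b) disclosure section
#' titles, (c) declared-conflict phrases ("maintains a financial relationship
#' with"), (d) no-conflict declarations ("nothing to disclose"), and (e)
#' conflict-associated words ("fees", "advisory board") evaluated only inside
#' the acknowledgments. The result's `subtype` is `"no_conflict"` when only
#' no-conflict wording fired, `"conflict_declared"` otherwise.
#'
#' @param article A [new_article()] object.
#' @param lexicon A lexicon.
#' @return A `transcreen_indicator_result`.
#' @examples
#' art <- new_article("a1", tibble::tibble(
#'   text = "The authors declare no competing interests.", zone = "footnote"))
#' detect_coi(art)
#' @export
detect_coi <- function(article, lexicon = default_lexicon()) {
  detect_indicator_(article, "coi", lexicon)
}

#' Detect a funding disclosure
#'
#' Finance wording belonging to conflict-of-interest disclosures is masked
#' first, then paragraph-level rules fire on (a) disclosure phrases, (b)
#' funding section titles, (c) foundation support, (d) author-referenced
#' statements, (e) thank-you statements, (f) awards and grants ("Grant no.
#' 12345"), (g) no-funding statements, and (h) funding words inside the
#' acknowledgments. `subtype` is `"no_funding"` when a no-funding statement
#' fired and no funds-received wording did, `"funds_received"` otherwise.
#'
#' @inheritParams detect_coi
#' @return A `transcreen_indicator_result`.
#' @export
detect_funding <- function(article, lexicon = default_lexicon()) {
  detect_indicator_(article, "funding", lexicon)
}

#' Detect a protocol registration statement
#'
#' Paragraph-level rules fire on (a) ClinicalTrials.gov and other trial
#' registries, (b) PROSPERO, (c) protocol/study registration regardless of
#' registry, (d) availability of the protocol on a register, (e)
#' registration-associated titles ("Trial registration: NCT12345678"), (f)
#' previously published protocols, and (g) registration identifiers inside
#' funding disclosures. Negation rules cancel non-registry "registry"
#' mentions ("hospital registry") and approval-only registration numbers.
#' Captured identifiers (NCT, CRD, ChiCTR, ...) are returned in
#' `registry_ids`.
#'
#' @inheritParams detect_coi
#' @return A `transcreen_indicator_result`.
#' @export
detect_registration <- function(article, lexicon = default_lexicon()) {
  detect_indicator_(article, "registration", lexicon)
}

#' Detect open data sharing
#'
#' Sentence-level rules (table and figure captions excluded) fire on (a)
#' general-purpose databases (figshare, Dryad), (b) field-specific databases
#' (dbSNP, GenBank), (c) online repositories holding data, (e) shared file
#' formats, (f) supplement-data language, and (g) availability-statement
#' language. Database and format mentions only count in a positive
#' availability context ("deposited", "can be downloaded"), and negated or
#' request-only sentences ("available upon request", "not deposited") never
#' count: the detector captures newly generated openly deposited data only.
#'
#' @inheritParams detect_coi
#' @return A `transcreen_indicator_result`.
#' @export
detect_data_sharing <- function(article, lexicon = default_lexicon()) {
  detect_indicator_(article, "data_sharing", lexicon)
}

#' Detect open code sharing
#'
#' Sentence-level rules fire on (c) code repositories (GitHub, Bitbucket)
#' and (d) code-availability language ("python script", "analysis code") in
#' positive context; negated or request-only statements do not count.
#'
#' @inheritParams detect_coi
#' @return A `transcreen_indicator_result`.
#' @export
detect_code_sharing <- function(article, lexicon = default_lexicon()) {
  detect_indicator_(article, "code_sharing", lexicon)
}

#' Extract the evidence text containing fired spans
#'
#' Maps character ranges that triggered a rule back to the verbatim evidence
#' a reader should see: the containing sentence for sentence-level detectors,
#' or the whole unit for paragraph-level detectors.
#'
#' @param unit A single normalized text unit.
#' @param fired_spans A two-column matrix or data frame of character ranges
#'   (start, end) within `unit`.
#' @param unit_kind `"sentence"` or `"paragraph"`.
#' @param lexicon A lexicon.
#' @return Character vector of evidence strings, one per span.
#' @examples
#' extract_evidence("A first claim. A second claim.", cbind(18, 23))
#' @export
extract_evidence <- function(unit, fired_spans, unit_kind = c("sentence", "paragraph"),
                             lexicon = default_lexicon()) {
  unit_kind <- match.arg(unit_kind)
  stopifnot(is.character(unit), length(unit) == 1)
  spans <- as.matrix(fired_spans)
  if (ncol(spans) != 2) stop("fired_spans must have two columns (start, end)")
  if (nrow(spans) == 0) return(character(0))
  if (any(spans[, 1] < 1 | spans[, 2] > nchar(unit) | spans[, 1] > spans[, 2])) {
    stop("span out of range for unit of length ", nchar(unit))
  }
  if (unit_kind == "paragraph") {
    return(rep(stringr::str_squish(unit), nrow(spans)))
  }
  toks <- tokenize_text(unit, "sentence", lexicon)
  vapply(seq_len(nrow(spans)), function(i) {
    hit <- which(toks$start <= spans[i, 1] & toks$end >= spans[i, 2])
    if (length(hit) == 0) hit <- which.min(abs(toks$start - spans[i, 1]))
    toks$text[hit[1]]
  }, character(1))
}
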