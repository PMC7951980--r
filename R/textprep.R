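# Text normalization, custom tokenization, and masking.
#
# The screening rules are sensitive to case and punctuation (both carry
# signal: section titles, "no. 123" style grant numbers), so normalization is
# deliberately light: no lowercasing, no stemming, no stop-word removal.

MASK_CHAR <- "\u2591" # reserved placeholder, guaranteed absent from all lexicons
PROTECT_CHAR <- "\ue000" # internal stand-in for a non-boundary full stop

#' Normalize article text
#'
#' Repairs damage typical of PDF-to-text conversion: undecodable bytes are
#' dropped, control characters removed, hyphenation across line breaks
#' rejoined, and line breaks inside a paragraph collapsed to single spaces.
#' Case, wording, and sentence punctuation are preserved. The function is
#' idempotent.
#'
#' @param text Character vector.
#' @return Character vector of the same length.
#' @examples
#' normalize_text("This study was\nregistered prospectively.")
#' @export
normalize_text <- function(text) {
  if (length(text) == 0) return(character(0))
  out <- enc2utf8(as.character(text))
  out[is.na(out)] <- ""
  out <- iconv(out, from = "UTF-8", to = "UTF-8", sub = "")
  # control characters other than whitespace carry no text
  out <- gsub("[\x01-\x08\x0b\x0c\x0e-\x1f\x7f]", "", out, perl = TRUE)
  # de-hyphenate words broken across lines ("regis-\ntered")
  out <- gsub("([a-z])-\\s*\n\\s*([a-z])", "\\1\\2", out, perl = TRUE)
  # remaining line breaks inside a unit are layout, not meaning
  stringr::str_squish(out)
}

#' Tokenize normalized text into sentences or paragraphs
#'
#' The sentence splitter is a custom rule set: it breaks after sentence-final
#' punctuation followed by whitespace, except after guarded abbreviations
#' ("no.", "et al.", "Fig.", ...), single-letter initials ("S.S."), and full
#' stops embedded in tokens ("ClinicalTrials.gov", "3.5"). Paragraph mode
#' returns the unit whole. Tokens partition the input: pasting them back with
#' single spaces reconstructs the normalized text.
#'
#' @param text A single normalized string.
#' @param unit_kind `"sentence"` or `"paragraph"`.
#' @param lexicon A lexicon (for the abbreviation guard list).
#' @return A tibble with columns `start`, `end` (character offsets into
#'   `text`) and `text` (the token).
#' @examples
#' tokenize_text("A first claim. A second claim.")
#' tokenize_text("Grant no. 12345 supported this work.")
#' @export
tokenize_text <- function(text, unit_kind = c("sentence", "paragraph"),
                          lexicon = default_lexicon()) {
  unit_kind <- match.arg(unit_kind)
  stopifnot(length(text) == 1)
  empty <- tibble::new_tibble(list(start = integer(0), end = integer(0),
                                   text = character(0)), nrow = 0L)
  if (is.na(text) || !nzchar(text)) return(empty)

  if (unit_kind == "paragraph") {
    loc <- stringr::str_locate(text, "\\S(.*\\S)?")
    if (is.na(loc[1, 1])) return(empty)
    return(tibble::new_tibble(list(start = loc[1, 1], end = loc[1, 2],
                                   text = substr(text, loc[1, 1], loc[1, 2])),
                              nrow = 1L))
  }

  protected <- protect_stops(text, lexicon)
  # boundary = sentence-final punctuation run followed by whitespace, or EOS
  bounds <- stringr::str_locate_all(protected, "[.!?]+(?=\\s)")[[1]][, "end"]
  bounds <- sort(unique(c(bounds, nchar(text))))
  starts <- as.integer(c(1L, head(bounds, -1L) + 1L))
  ends <- as.integer(bounds)
  txt <- substr(rep(text, length(starts)), starts, ends)
  keep <- grepl("\\S", txt)
  starts <- starts[keep]; ends <- ends[keep]; txt <- txt[keep]
  if (length(txt) == 0) return(empty)
  lead <- nchar(sub("^(\\s*).*$", "\\1", txt))
  trail <- nchar(sub("^.*?(\\s*)$", "\\1", txt))
  starts <- starts + lead
  ends <- ends - trail
  txt <- substr(rep(text, length(starts)), starts, ends)
  tibble::new_tibble(list(start = starts, end = ends, text = txt),
                     nrow = length(txt))
}

# replace full stops that do not end a sentence with a placeholder of equal
# length so offsets are unchanged
protect_stops <- function(text, lexicon) {
  out <- text
  # dots attached to a following non-space character: decimals, domains, ids
  out <- gsub("\\.(?=\\S)", PROTECT_CHAR, out, perl = TRUE)
  # guarded abbreviations ("no. 123" is not a boundary)
  abbr <- lexicon$abbreviations
  abbr <- abbr[nzchar(abbr) & endsWith(abbr, ".")]
  if (length(abbr) > 0) {
    stems <- rex_escape(sub("\\.$", "", abbr))
    pat <- paste0("(?<![A-Za-z])(", paste(stems, collapse = "|"), ")\\.")
    out <- gsub(pat, paste0("\\1", PROTECT_CHAR), out, perl = TRUE)
  }
  # single-letter initials: "S." in "S.S." or "J. D. Smith"
  out <- gsub("(?<![A-Za-z])([A-Z])\\.", paste0("\\1", PROTECT_CHAR), out, perl = TRUE)
  out
}

rex_escape <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Mask text spans that would mislead another indicator's patterns
#'
#' Spans matching the mask specifications registered for `indicator` are
#' replaced in place by a neutral placeholder of equal length, so all
#' character offsets (and therefore evidence extraction) are preserved. The
#' shipped configuration masks finance wording inside conflict-of-interest
#' disclosures ("S.S. has financial relationships with GSK") before funding
#' detection, so such sentences are not mislabelled as funding disclosures.
#' Masking is idempotent.
#'
#' @param text Character vector.
#' @param indicator One of `"data_sharing"`, `"code_sharing"`, `"coi"`,
#'   `"funding"`, `"registration"`.
#' @param lexicon A lexicon.
#' @return Character vector, each element the same length as its input.
#' @examples
#' apply_masks("S.S. has financial relationships with GSK", "funding")
#' @export
apply_masks <- function(text, indicator, lexicon = default_lexicon()) {
  if (!is.character(indicator) || length(indicator) != 1 ||
      !indicator %in% INDICATORS) {
    stop("unknown indicator: ", paste(indicator, collapse = ", "), call. = FALSE)
  }
  masks <- lexicon$masks
  applies <- vapply(strsplit(masks$applies_to, ";", fixed = TRUE),
                    function(x) indicator %in% trimws(x), logical(1))
  masks <- masks[applies, , drop = FALSE]
  if (nrow(masks) == 0) return(text)
  out <- text
  for (i in seq_len(nrow(masks))) {
    pat <- lex_regex(masks$pattern[i], masks$ignore_case[i])
    out <- vapply(out, function(s) {
      spans <- stringr::str_locate_all(s, pat)[[1]]
      mask_spans(s, spans)
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

# overwrite [start, end] spans with the mask placeholder, preserving length
mask_spans <- function(s, spans) {
  if (is.null(spans) || nrow(spans) == 0 || is.na(s)) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(spans))) {
    chars[spans[i, 1]:spans[i, 2]] <- MASK_CHAR
  }
  paste(chars, collapse = "")
}

# drop a trailing reference list from raw plain text (a "References"-style
# heading line through end of file)
strip_reference_tail <- function(raw) {
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  hit <- grep("^\\s*(References|REFERENCES|Bibliography|Literature\\s+Cited|Works\\s+Cited)\\s*[:.]?\\s*$",
              lines)
  if (length(hit) > 0) lines <- lines[seq_len(hit[1] - 1L)]
  paste(lines, collapse = "\n")
}
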