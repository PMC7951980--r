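#' Load the pattern lexicon
#'
#' The detectors are driven entirely by editable configuration shipped under
#' `inst/extdata/patterns/`: one tab-separated file of labelling patterns per
#' indicator (columns `indicator`, `code`, `polarity`, `zone`, `needs_context`,
#' `ignore_case`, `pattern`), plus masking specifications, section-title
#' lexicons, a sentence-tokenizer abbreviation guard list, registry-identifier
#' grammars, markup-tag XPaths, and label alias groups. Patterns are data, not
#' code: a lexicon can be re-authored without touching the package.
#'
#' Entries have one of three polarities: `positive` entries fire a category
#' code; `context` entries list availability cues that `needs_context = 1`
#' entries must co-occur with inside a sentence; `negation` entries cancel
#' hits (a negated sentence is dropped; in paragraph mode the negated span is
#' masked before positive matching).
#'
#' @param dir Directory holding the configuration files. Defaults to the
#'   lexicon shipped with the package.
#' @return A list of class `transcreen_lexicon` with elements `patterns`,
#'   `masks`, `section_titles`, `abbreviations`, `registry_ids`, `xml_tags`,
#'   `aliases`, and `version`.
#' @examples
#' lex <- load_lexicon()
#' nrow(lex$patterns)
#' @export
load_lexicon <- function(dir = system.file("extdata", "patterns", package = "transcreen")) {
  stopifnot(dir.exists(dir))
  read_tsv_ <- function(name) {
    path <- file.path(dir, name)
    utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                      comment.char = "", encoding = "UTF-8")
  }
  ind_files <- paste0(INDICATORS, ".tsv")
  patterns <- dplyr::bind_rows(lapply(ind_files, read_tsv_))
  patterns <- tibble::as_tibble(patterns)
  stopifnot(all(patterns$polarity %in% c("positive", "context", "negation")),
            all(patterns$zone %in% c("all", "ack", "heading")))
  # every category code needs at least one positive entry
  pos <- patterns[patterns$polarity == "positive", ]
  stopifnot(nrow(pos) > 0, all(nzchar(pos$code)))

  lex <- list(
    patterns = patterns,
    masks = tibble::as_tibble(read_tsv_("masks.tsv")),
    section_titles = tibble::as_tibble(read_tsv_("section_titles.tsv")),
    abbreviations = readLines(file.path(dir, "abbreviations.txt"), encoding = "UTF-8"),
    registry_ids = tibble::as_tibble(read_tsv_("registry_ids.tsv")),
    xml_tags = tibble::as_tibble(read_tsv_("xml_tags.tsv")),
    aliases = tibble::as_tibble(read_tsv_("label_aliases.tsv")),
    version = "1.0"
  )
  class(lex) <- "transcreen_lexicon"
  lex
}

#' @export
print.transcreen_lexicon <- function(x, ...) {
  cat("<transcreen_lexicon> version", x$version, "\n")
  counts <- table(x$patterns$indicator[x$patterns$polarity == "positive"],
                  x$patterns$code[x$patterns$polarity == "positive"])
  cat(sprintf("  %d pattern entries (%d positive) across %d indicators\n",
              nrow(x$patterns), sum(x$patterns$polarity == "positive"),
              length(unique(x$patterns$indicator))))
  cat(sprintf("  %d masks, %d section-title kinds, %d abbreviation guards, %d registry grammars\n",
              nrow(x$masks), length(unique(x$section_titles$kind)),
              length(x$abbreviations), nrow(x$registry_ids)))
  invisible(counts)
  invisible(x)
}

# session cache: the shipped lexicon is immutable
default_lexicon <- function() {
  if (is.null(the$lexicon)) the$lexicon <- load_lexicon()
  the$lexicon
}

# compile a lexicon row into a stringr pattern
lex_regex <- function(pattern, ignore_case) {
  stringr::regex(pattern, ignore_case = isTRUE(ignore_case == 1 | ignore_case == TRUE))
}
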