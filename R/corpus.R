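# Batch screening of corpora into flat per-article records, label
# standardization, and prevalence aggregation.

IND_PREFIX <- c(data_sharing = "data", code_sharing = "code", coi = "coi",
                funding = "fund", registration = "reg")
PRED_COLS <- c(data_sharing = "is_data_pred", code_sharing = "is_code_pred",
               coi = "is_coi_pred", funding = "is_fund_pred",
               registration = "is_register_pred")
TEXT_COLS <- c(data_sharing = "data_text", code_sharing = "code_text",
               coi = "coi_text", funding = "fund_text",
               registration = "register_text")

# stable category-flag column names, derived from the lexicon
category_columns <- function(lexicon = default_lexicon()) {
  pos <- lexicon$patterns[lexicon$patterns$polarity == "positive", ]
  out <- character(0)
  for (ind in INDICATORS) {
    codes <- sort(unique(pos$code[pos$indicator == ind]))
    out <- c(out, paste(IND_PREFIX[[ind]], codes, sep = "_"))
  }
  out
}

empty_record <- function(lexicon = default_lexicon()) {
  rec <- tibble::tibble(
    article_id = NA_character_, pmid = NA_character_, pmcid = NA_character_,
    journal = NA_character_, publisher = NA_character_, year = NA_integer_,
    country = NA_character_, article_type = NA_character_, is_research = NA,
    is_data_pred = FALSE, is_code_pred = FALSE, is_coi_pred = FALSE,
    is_fund_pred = FALSE, is_register_pred = FALSE,
    data_text = "", code_text = "", coi_text = "", fund_text = "",
    register_text = "", coi_subtype = NA_character_,
    fund_subtype = NA_character_, register_ids = ""
  )
  for (col in category_columns(lexicon)) rec[[col]] <- FALSE
  rec$failed <- FALSE
  rec$fail_reason <- ""
  rec
}

#' Screen one article for all five transparency indicators
#'
#' Composes reading, preprocessing, and the five detectors into a single
#' flat record: one presence flag and one evidence text per indicator, one
#' boolean per fired category code, subtype fields, captured registry
#' identifiers, and pass-through metadata. A document that cannot be parsed
#' yields a record flagged `failed` (with the reason) rather than an error,
#' so batch screening continues.
#'
#' @param document A path to a document, a string of content, or a
#'   [new_article()] object.
#' @param format `"jats"` or `"text"` (ignored when `document` is already an
#'   article).
#' @param article_id Identifier override.
#' @param lexicon A lexicon.
#' @return A one-row tibble.
#' @export
screen_article <- function(document, format = c("jats", "text"),
                           article_id = NULL, lexicon = default_lexicon()) {
  format <- match.arg(format)
  rec <- empty_record(lexicon)
  art <- tryCatch({
    if (inherits(document, "transcreen_article")) {
      document
    } else if (format == "jats") {
      read_jats(document, article_id = article_id)
    } else {
      id <- if (is.null(article_id)) {
        if (file.exists(document)) basename(document) else "unidentified-article"
      } else article_id
      read_plaintext(document, id, lexicon)
    }
  }, error = function(e) e)
  if (inherits(art, "error")) {
    rec$article_id <- if (!is.null(article_id)) article_id else
      if (is.character(document) && file.exists(document)) basename(document) else "unreadable"
    rec$failed <- TRUE
    rec$fail_reason <- conditionMessage(art)
    return(rec)
  }

  rec$article_id <- art$article_id
  rec$pmid <- art$pmid; rec$pmcid <- art$pmcid
  rec$journal <- art$journal; rec$publisher <- art$publisher
  rec$year <- art$year; rec$article_type <- art$article_type

  for (ind in INDICATORS) {
    res <- detect_indicator_(art, ind, lexicon)
    rec[[PRED_COLS[[ind]]]] <- res$present
    rec[[TEXT_COLS[[ind]]]] <- paste(res$evidence, collapse = " | ")
    for (code in res$categories) {
      col <- paste(IND_PREFIX[[ind]], code, sep = "_")
      if (col %in% names(rec)) rec[[col]] <- TRUE
    }
    if (ind == "coi") rec$coi_subtype <- res$subtype
    if (ind == "funding") rec$fund_subtype <- res$subtype
    if (ind == "registration") rec$register_ids <- paste(res$registry_ids, collapse = ";")
  }
  rec
}

#' Screen a corpus of articles
#'
#' Screens documents in batches, optionally in parallel, into one record per
#' input. Output order always matches input order and is identical for any
#' worker count. Unreadable files produce failed records, never an abort.
#'
#' @param paths Character vector of file paths (or of document content).
#' @param format `"jats"` or `"text"`.
#' @param batch_size Number of articles per processing batch.
#' @param workers Number of parallel workers (forked; falls back to serial
#'   where forking is unavailable).
#' @param lexicon A lexicon.
#' @param quiet Suppress per-batch progress messages.
#' @return A tibble with one row per element of `paths`.
#' @export
screen_corpus <- function(paths, format = c("jats", "text"), batch_size = 4096,
                          workers = 1, lexicon = default_lexicon(),
                          quiet = FALSE) {
  format <- match.arg(format)
  stopifnot(batch_size >= 1, workers >= 1)
  if (length(paths) == 0) return(empty_record(lexicon)[0, ])
  force(lexicon)
  batches <- split(seq_along(paths), ceiling(seq_along(paths) / batch_size))
  out <- vector("list", length(batches))
  t0 <- Sys.time()
  for (b in seq_along(batches)) {
    idx <- batches[[b]]
    one <- function(i) screen_article(paths[i], format, lexicon = lexicon)
    rows <- if (workers > 1 && .Platform$OS.type == "unix") {
      parallel::mclapply(idx, one, mc.cores = workers, mc.preschedule = TRUE)
    } else {
      lapply(idx, one)
    }
    out[[b]] <- dplyr::bind_rows(rows)
    if (!quiet) {
      message(sprintf("screened batch %d/%d (%d articles)", b, length(batches),
                      length(idx)))
    }
  }
  res <- dplyr::bind_rows(out)
  if (!quiet) {
    dt <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    message(sprintf("screened %d articles in %.1fs (%.3fs/article)",
                    nrow(res), dt, dt / nrow(res)))
  }
  res
}

#' Standardize free-text labels
#'
#' Archive metadata reports the same label in many variants ("USA",
#' "United States", "U.S.A.", "Texas, USA"). Variants are grouped as the same
#' canonical label when they share an alias group from the lexicon, reduce to
#' the same punctuation/case-stripped key, or contain a more frequent label
#' as a whole-token substring. Within a group, every variant occurring at
#' least `min_count` times maps to the group's most common form
#' (lexicographically first on ties); rarer variants map to themselves.
#'
#' @param values Character vector of raw labels (with repetitions).
#' @param min_count Minimum number of occurrences for a variant to be
#'   standardized.
#' @param lexicon A lexicon (for the alias groups).
#' @return A named character vector: names are the distinct input values,
#'   values the standardized labels.
#' @examples
#' standardize_labels(c(rep("USA", 50), rep("United States", 30), rep("U.S.A.", 5)))
#' @export
standardize_labels <- function(values, min_count = 20,
                               lexicon = default_lexicon()) {
  values <- values[!is.na(values)]
  if (length(values) == 0) return(setNames(character(0), character(0)))
  counts <- sort(table(values), decreasing = TRUE)
  distinct <- names(counts)

  norm_key <- function(x) gsub("[^a-z0-9]+", "", tolower(x))
  aliases <- lexicon$aliases
  alias_group <- setNames(aliases$group, tolower(trimws(aliases$alias)))
  group <- vapply(distinct, function(v) {
    g <- alias_group[tolower(trimws(v))]
    if (!is.na(g)) paste0("alias:", g) else paste0("key:", norm_key(v))
  }, character(1))

  # containment: a rarer, longer variant that embeds a more frequent label
  # as a whole token joins that label's group ("Texas, USA" -> "USA")
  for (i in seq_along(distinct)) {
    v <- distinct[i]
    for (j in seq_along(distinct)) {
      if (i == j) next
      w <- distinct[j]
      if (counts[j] <= counts[i] || nchar(w) >= nchar(v)) next
      if (grepl(paste0("(^|[^A-Za-z])", rex_escape(w), "($|[^A-Za-z])"), v)) {
        group[i] <- group[j]
        break
      }
    }
  }

  mapping <- setNames(distinct, distinct)
  for (g in unique(group)) {
    members <- distinct[group == g]
    mcount <- counts[members]
    standard <- sort(members[mcount == max(mcount)], method = "radix")[1]
    eligible <- members[mcount >= min_count]
    mapping[eligible] <- standard
  }
  mapping
}

#' Proportion of a count, on the printed-percentage scale
#'
#' @param n_positive,n_total Non-negative counts, `n_total > 0`.
#' @param digits Decimal places for the rounded percentage.
#' @return A tibble with `n_positive`, `n_total`, `proportion` (unrounded)
#'   and `pct` (percentage rounded to `digits`).
#' @examples
#' indicator_prevalence(243783, 2751420) # 8.9%
#' @export
indicator_prevalence <- function(n_positive, n_total, digits = 1) {
  stopifnot(all(n_total > 0), all(n_positive >= 0), all(n_positive <= n_total))
  prop <- n_positive / n_total
  tibble::tibble(n_positive = n_positive, n_total = n_total,
                 proportion = prop, pct = round(100 * prop, digits))
}

#' Aggregate indicator prevalence over grouping variables
#'
#' @param records A tibble of screening records (from [screen_corpus()]).
#' @param group_keys Character vector of grouping column names (empty for a
#'   corpus-wide total). Rows with a missing key are excluded.
#' @param min_group Groups smaller than this are flagged `below_min`.
#' @return A tibble with one row per group: `n_total`, and per indicator the
#'   positive count and unrounded proportion.
#' @export
prevalence_by <- function(records, group_keys = character(0), min_group = 100) {
  stopifnot(is.data.frame(records))
  df <- records
  if (!is.null(df[["failed"]])) df <- df[!df$failed, , drop = FALSE]
  for (k in group_keys) df <- df[!is.na(df[[k]]), , drop = FALSE]
  if (nrow(df) == 0) {
    return(tibble::tibble())
  }
  summar <- function(d) {
    out <- tibble::tibble(n_total = nrow(d))
    for (ind in INDICATORS) {
      n <- sum(d[[PRED_COLS[[ind]]]], na.rm = TRUE)
      out[[paste0(IND_PREFIX[[ind]], "_n")]] <- n
      out[[paste0(IND_PREFIX[[ind]], "_prop")]] <- n / nrow(d)
    }
    out
  }
  if (length(group_keys) == 0) {
    res <- summar(df)
  } else {
    res <- df |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_keys))) |>
      dplyr::group_modify(~ summar(.x)) |>
      dplyr::ungroup()
  }
  res$below_min <- res$n_total < min_group
  res
}

#' Centered moving average of a yearly series
#'
#' For an even window `w`, the window at year `y` spans `y - w/2` through
#' `y + w/2 - 1`; edge years use the truncated available window.
#'
#' @param series Numeric vector indexed by consecutive years (names are
#'   preserved).
#' @param window Window width in years (>= 1).
#' @return Numeric vector of the same length and names as `series`.
#' @examples
#' centered_moving_average(c(`1` = 0, `2` = 0, `3` = 1, `4` = 1), window = 4)
#' @export
centered_moving_average <- function(series, window = 4) {
  if (!is.numeric(window) || length(window) != 1 || window < 1) {
    stop("window must be a single integer >= 1")
  }
  window <- as.integer(window)
  n <- length(series)
  left <- floor(window / 2)
  right <- window - left - 1L
  out <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - left)
    hi <- min(n, i + right)
    mean(series[lo:hi])
  }, numeric(1))
  names(out) <- names(series)
  out
}
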