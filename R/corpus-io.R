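#' Normalize a raw utterance transcription
#'
#' Applies the transcript normalization used throughout the package: the
#' string is lower-cased, every character outside `[a-z0-9' ]` is removed
#' (so punctuation disappears but apostrophes in contractions survive), and
#' the result is split on whitespace. Utterances containing an
#' incomprehensible-speech marker (CHAT-style `xxx`, `yyy`, `www` by
#' default), or that are empty after cleaning, are dropped.
#'
#' @param raw Character vector of raw utterance lines.
#' @param drop_markers Character vector of word-level markers whose presence
#'   drops the whole utterance.
#' @return A list, one element per input line: a character vector of
#'   normalized words, or `NULL` for a dropped utterance.
#' @examples
#' normalize_utterance("Look at the Doggy !")
#' normalize_utterance("xxx")
#' @export
normalize_utterance <- function(raw, drop_markers = c("xxx", "yyy", "www")) {
  cleaned <- stringr::str_to_lower(raw)
  cleaned <- stringr::str_replace_all(cleaned, "[^a-z0-9' ]", " ")
  words <- stringr::str_split(stringr::str_squish(cleaned), stringr::fixed(" "))
  purrr::map(words, function(w) {
    w <- w[nzchar(w)]
    if (length(w) == 0L || any(w %in% drop_markers)) NULL else w
  })
}

#' Normalize a transcript table into a corpus tibble
#'
#' Takes a raw transcript table (one row per utterance) and returns the
#' normalized corpus: lower-cased, punctuation-free utterances stored as a
#' single space-separated string per row. Rows that normalize to nothing or
#' contain incomprehensible-speech markers are dropped; the number of drops
#' is attached as the `n_dropped` attribute and reported.
#'
#' @param data A data frame with at least `utterance_text`; columns
#'   `speaker_role`, `child_age_months` and `corpus_id` are carried through.
#' @param drop_markers See [normalize_utterance()].
#' @param quiet Suppress the drop-count message.
#' @return A tibble with columns `utterance`, `speaker_role`,
#'   `child_age_months`, `corpus_id`.
#' @export
normalize_corpus <- function(data, drop_markers = c("xxx", "yyy", "www"),
                             quiet = FALSE) {
  stopifnot(is.data.frame(data))
  if (!"utterance_text" %in% names(data) && "utterance" %in% names(data)) {
    data <- dplyr::rename(data, utterance_text = "utterance")
  }
  if (!"utterance_text" %in% names(data)) {
    stop("`data` must have an `utterance_text` column", call. = FALSE)
  }
  words <- normalize_utterance(data$utterance_text, drop_markers)
  keep <- !purrr::map_lgl(words, is.null)
  out <- tibble::tibble(
    utterance = purrr::map_chr(words[keep], paste, collapse = " "),
    speaker_role = if ("speaker_role" %in% names(data)) {
      data$speaker_role[keep]
    } else {
      rep(NA_character_, sum(keep))
    },
    child_age_months = if ("child_age_months" %in% names(data)) {
      as.numeric(data$child_age_months[keep])
    } else {
      rep(NA_real_, sum(keep))
    },
    corpus_id = if ("corpus_id" %in% names(data)) {
      as.character(data$corpus_id[keep])
    } else {
      rep(NA_character_, sum(keep))
    }
  )
  attr(out, "n_dropped") <- sum(!keep)
  if (!quiet && sum(!keep) > 0) {
    message(sum(!keep), " utterance(s) dropped during normalization")
  }
  out
}

#' Read a tabular transcript export
#'
#' Reads a CSV/TSV transcript table in the childes-db export style with
#' columns `utterance_text`, `speaker_role`, `target_child_age_months` (or
#' `child_age_months`) and `corpus_id`, keeps only mother/father utterances,
#' drops rows without child-age information, and normalizes the text.
#'
#' @param path Path to a CSV or TSV file (sniffed from the extension).
#' @param roles Speaker roles to keep.
#' @param drop_markers See [normalize_utterance()].
#' @param quiet Suppress count messages.
#' @return A normalized corpus tibble (see [normalize_corpus()]) with
#'   attributes `n_role_dropped`, `n_no_age` and `n_dropped`.
#' @export
read_transcript_table <- function(path, roles = c("mother", "father"),
                                  drop_markers = c("xxx", "yyy", "www"),
                                  quiet = FALSE) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if ("target_child_age_months" %in% names(raw)) {
    raw <- dplyr::rename(raw, child_age_months = "target_child_age_months")
  }
  for (col in c("utterance_text", "speaker_role", "child_age_months")) {
    if (!col %in% names(raw)) {
      stop("transcript table is missing required column `", col, "`",
           call. = FALSE)
    }
  }
  if (!"corpus_id" %in% names(raw)) raw$corpus_id <- NA_character_
  role_ok <- tolower(as.character(raw$speaker_role)) %in% tolower(roles)
  n_role_dropped <- sum(!role_ok)
  raw <- raw[role_ok, , drop = FALSE]
  age <- suppressWarnings(as.numeric(raw$child_age_months))
  n_no_age <- sum(is.na(age))
  raw <- raw[!is.na(age), , drop = FALSE]
  out <- normalize_corpus(raw, drop_markers, quiet = quiet)
  attr(out, "n_role_dropped") <- n_role_dropped
  attr(out, "n_no_age") <- n_no_age
  if (!quiet) {
    message(nrow(out), " utterances retained (", n_role_dropped,
            " non-target-role rows, ", n_no_age, " ageless rows dropped)")
  }
  out
}

#' Write / read a corpus as JSON lines
#'
#' One JSON object per line with fields `words` (array), `speaker_role`,
#' `child_age_months`, `corpus_id`. The round trip is lossless.
#'
#' @param corpus A corpus tibble (see [normalize_corpus()]).
#' @param path Output file path.
#' @return `write_corpus()` returns `path` invisibly; `read_corpus()` a
#'   corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(is.data.frame(corpus), "utterance" %in% names(corpus))
  lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      words = strsplit(corpus$utterance[i], " ", fixed = TRUE)[[1]],
      speaker_role = corpus$speaker_role[i],
      child_age_months = corpus$child_age_months[i],
      corpus_id = corpus$corpus_id[i]
    ), auto_unbox = TRUE, null = "null", digits = NA)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- purrr::map(lines, jsonlite::fromJSON)
  null_chr <- function(x) if (is.null(x)) NA_character_ else as.character(x)
  null_num <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  tibble::tibble(
    utterance = purrr::map_chr(recs, ~ paste(.x$words, collapse = " ")),
    speaker_role = purrr::map_chr(recs, ~ null_chr(.x$speaker_role)),
    child_age_months = purrr::map_dbl(recs, ~ null_num(.x$child_age_months)),
    corpus_id = purrr::map_chr(recs, ~ null_chr(.x$corpus_id))
  )
}

#' Assign utterances to 3-month age bins
#'
#' Each utterance is assigned to the bin whose center (a multiple of 3
#' months, 3..84) is nearest, using half-open intervals
#' `[center - 1.5, center + 1.5)`. Utterances outside `[1.5, 85.5)` are
#' excluded; their count is attached as attribute `n_excluded`.
#'
#' @param corpus A corpus tibble with `child_age_months`.
#' @param centers Integer bin centers in months.
#' @return The corpus tibble with an added integer `age_bin` column,
#'   excluded rows removed.
#' @export
bin_by_age <- function(corpus, centers = seq(3L, 84L, by = 3L)) {
  stopifnot(is.data.frame(corpus), "child_age_months" %in% names(corpus))
  age <- corpus$child_age_months
  # floor(x + .5) rather than round(): interval edges (odd multiples of 1.5)
  # must round up so [center - 1.5, center + 1.5) is half-open
  bin <- as.integer(3L * floor(age / 3 + 0.5))
  ok <- !is.na(age) & bin %in% centers &
    age >= (bin - 1.5) & age < (bin + 1.5)
  out <- corpus[ok, , drop = FALSE]
  out$age_bin <- bin[ok]
  out <- tibble::as_tibble(out)
  attr(out, "n_excluded") <- sum(!ok)
  out
}
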