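pad_utt <- function(u) paste0(" ", u, " ")

#' Novelty of generated utterances against a training corpus
#'
#' For each generated utterance (its word string, final stop excluded),
#' checks whether the word sequence occurs as a contiguous subsequence
#' inside any single training utterance (matches never cross training
#' utterance boundaries; set `span_utterances = TRUE` to search the
#' concatenated stream instead). Reports the proportion of unattested
#' ("novel") utterances by utterance length, together with the binomial
#' standard deviation of the novelty indicator and the count at each
#' length.
#'
#' @param generated,training Corpus tibbles (see [normalize_corpus()]).
#' @param span_utterances Allow a match to span adjacent training
#'   utterances (concatenated in corpus order).
#' @return A tibble: `length`, `n`, `novelty_rate`, `sd`.
#' @export
novelty_profile <- function(generated, training, span_utterances = FALSE) {
  stopifnot(is.data.frame(generated), is.data.frame(training))
  haystack <- if (span_utterances) {
    pad_utt(paste(training$utterance, collapse = " "))
  } else {
    # separated by newline so a padded needle cannot bridge utterances
    paste(pad_utt(training$utterance), collapse = "\n")
  }
  needles <- pad_utt(generated$utterance)
  attested <- stringr::str_detect(haystack, stringr::fixed(needles))
  len <- lengths(strsplit(generated$utterance, " ", fixed = TRUE))
  tibble::tibble(length = len, novel = !attested) |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(
      n = dplyr::n(),
      novelty_rate = mean(.data$novel),
      sd = sqrt(.data$novelty_rate * (1 - .data$novelty_rate)),
      .groups = "drop"
    )
}

#' Proportion of training utterances that occur only once
#'
#' The reference curve for novelty analysis: among the training
#' utterances of each length, the proportion whose word string appears
#' exactly once in the whole training corpus.
#'
#' @param training A corpus tibble.
#' @return A tibble: `length`, `n`, `unique_rate`, `sd`.
#' @export
uniqueness_profile <- function(training) {
  stopifnot(is.data.frame(training))
  counts <- table(training$utterance)
  once <- counts[training$utterance] == 1
  len <- lengths(strsplit(training$utterance, " ", fixed = TRUE))
  tibble::tibble(length = len, once = as.vector(once)) |>
    dplyr::group_by(.data$length) |>
    dplyr::summarise(
      n = dplyr::n(),
      unique_rate = mean(.data$once),
      sd = sqrt(.data$unique_rate * (1 - .data$unique_rate)),
      .groups = "drop"
    )
}
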