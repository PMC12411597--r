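#' Write / read gold token tables as CoNLL-U
#'
#' `to_conllu()` serializes a gold token tibble (one row per token, columns
#' `utt_id`, `position`, `form`, `lemma`, `upos`, `head`, `deprel`; see
#' [sample_corpus()]) as CoNLL-U text: one token line per word with ID,
#' FORM, LEMMA, UPOS, HEAD and DEPREL filled and the remaining fields `_`,
#' sentences separated by blank lines. `read_conllu()` parses such text
#' back into the same tabular shape; the round trip is lossless for the
#' fields the package uses.
#'
#' @param gold Gold token tibble.
#' @param path Optional output path; when `NULL` the text is returned.
#' @return `to_conllu()`: the CoNLL-U text as a character scalar
#'   (invisibly when written to `path`). `read_conllu()`: a gold token
#'   tibble with `utt_id`, `position`, `form`, `lemma`, `upos`, `head`,
#'   `deprel` and, when a `# child_age_months` comment is present, the age.
#' @export
to_conllu <- function(gold, path = NULL) {
  stopifnot(is.data.frame(gold))
  blocks <- gold |>
    dplyr::group_by(.data$utt_id) |>
    dplyr::group_map(function(g, key) {
      g <- g[order(g$position), ]
      hdr <- c(
        paste0("# sent_id = ", key$utt_id),
        if ("child_age_months" %in% names(g)) {
          paste0("# child_age_months = ", g$child_age_months[1])
        }
      )
      lines <- paste(g$position, g$form, g$lemma, g$upos, "_", "_",
                     g$head, g$deprel, "_", "_", sep = "\t")
      paste(c(hdr, lines, ""), collapse = "\n")
    })
  text <- paste(unlist(blocks), collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

#' @rdname to_conllu
#' @export
read_conllu <- function(path) {
  lines <- if (length(path) == 1 && !grepl("\n", path, fixed = TRUE) &&
               file.exists(path)) {
    readLines(path, encoding = "UTF-8")
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  sent <- 0L
  age <- NA_real_
  in_sent <- FALSE
  rows <- vector("list", length(lines))
  k <- 0L
  for (ln in lines) {
    if (!nzchar(ln)) {
      in_sent <- FALSE
      next
    }
    if (startsWith(ln, "#")) {
      if (!in_sent) {
        sent <- sent + 1L
        age <- NA_real_
        in_sent <- TRUE
      }
      m <- regmatches(ln, regexec("^# child_age_months = (.+)$", ln))[[1]]
      if (length(m) == 2) age <- as.numeric(m[2])
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed CoNLL-U token line: ", ln,
                            call. = FALSE)
    if (grepl("[.-]", f[1])) next  # skip multiword/empty-node lines
    if (!in_sent) {
      sent <- sent + 1L
      age <- NA_real_
      in_sent <- TRUE
    }
    k <- k + 1L
    rows[[k]] <- tibble::tibble(
      utt_id = sent, child_age_months = age,
      position = as.integer(f[1]), form = f[2], lemma = f[3], upos = f[4],
      head = as.integer(f[7]), deprel = f[8]
    )
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

#' Check Universal Dependencies tree well-formedness
#'
#' Verifies that every utterance in a gold token table has exactly one
#' root (`head == 0`), in-range heads, and an acyclic head graph.
#'
#' @param gold Gold token tibble.
#' @return Invisibly `TRUE`; stops naming the first offending utterance.
#' @export
check_trees <- function(gold) {
  for (id in unique(gold$utt_id)) {
    g <- gold[gold$utt_id == id, ]
    g <- g[order(g$position), ]
    n <- nrow(g)
    if (sum(g$head == 0) != 1) {
      stop("utterance ", id, ": expected exactly one root", call. = FALSE)
    }
    if (any(g$head < 0 | g$head > n)) {
      stop("utterance ", id, ": head index out of range", call. = FALSE)
    }
    # walk to the root from every token; a cycle never terminates
    for (i in seq_len(n)) {
      seen <- logical(n)
      j <- i
      while (j != 0) {
        if (seen[j]) stop("utterance ", id, ": cyclic head graph",
                          call. = FALSE)
        seen[j] <- TRUE
        j <- g$head[j]
      }
    }
  }
  invisible(TRUE)
}
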