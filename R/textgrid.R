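#' Read / write Praat TextGrid interval tiers
#'
#' Minimal long-format TextGrid support covering interval tiers, the
#' output format of forced aligners. `read_textgrid()` returns all
#' interval tiers as one tibble; empty-label intervals (silences) are kept
#' so callers can filter.
#'
#' @param path TextGrid file path.
#' @return A tibble: `tier`, `label`, `start`, `end` (seconds).
#' @export
read_textgrid <- function(path) {
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  num <- function(ln) as.numeric(sub(".*= *", "", ln))
  str <- function(ln) {
    m <- regmatches(ln, regexec("\"(.*)\"", ln))[[1]]
    if (length(m) == 2) m[2] else ""
  }
  tier <- NA_character_
  rows <- list()
  cur <- list()
  for (ln in lines) {
    if (grepl("^name *=", ln)) {
      tier <- str(ln)
    } else if (grepl("^intervals \\[", ln)) {
      cur <- list()
    } else if (grepl("^xmin *=", ln)) {
      cur$start <- num(ln)
    } else if (grepl("^xmax *=", ln)) {
      cur$end <- num(ln)
    } else if (grepl("^text *=", ln)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tier = tier, label = str(ln), start = cur$start, end = cur$end)
    }
  }
  out <- dplyr::bind_rows(rows)
  # the file header's own xmin/xmax are caught before any tier is named
  out[!is.na(out$tier), , drop = FALSE]
}

#' @rdname read_textgrid
#' @param alignment A tibble with `tier`, `label`, `start`, `end`; one
#'   interval tier is written per distinct `tier` value, in order of first
#'   appearance.
#' @export
write_textgrid <- function(alignment, path) {
  stopifnot(all(c("tier", "label", "start", "end") %in% names(alignment)))
  tiers <- unique(alignment$tier)
  xmin <- min(alignment$start)
  xmax <- max(alignment$end)
  out <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    paste0("xmin = ", xmin),
    paste0("xmax = ", xmax),
    "tiers? <exists>",
    paste0("size = ", length(tiers)),
    "item []:"
  )
  for (k in seq_along(tiers)) {
    g <- alignment[alignment$tier == tiers[k], , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    out <- c(out,
      paste0("    item [", k, "]:"),
      "        class = \"IntervalTier\"",
      paste0("        name = \"", tiers[k], "\""),
      paste0("        xmin = ", min(g$start)),
      paste0("        xmax = ", max(g$end)),
      paste0("        intervals: size = ", nrow(g)))
    for (i in seq_len(nrow(g))) {
      out <- c(out,
        paste0("        intervals [", i, "]:"),
        paste0("            xmin = ", format(g$start[i], digits = 12)),
        paste0("            xmax = ", format(g$end[i], digits = 12)),
        paste0("            text = \"", g$label[i], "\""))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write a pitch track CSV
#'
#' Columns `time_s`, `f0_hz`, `voiced` (0/1); `f0_hz` may be 0 or NA on
#' unvoiced frames.
#'
#' @param path CSV path.
#' @return A tibble with `time_s`, `f0_hz` (numeric) and `voiced`
#'   (logical).
#' @export
read_pitch <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("time_s", "f0_hz", "voiced") %in% names(out)))
  out$voiced <- as.logical(out$voiced)
  out
}

#' @rdname read_pitch
#' @param track A pitch-track tibble.
#' @export
write_pitch <- function(track, path) {
  out <- tibble::tibble(time_s = track$time_s, f0_hz = track$f0_hz,
                        voiced = as.integer(track$voiced))
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' ARPABET vowel nuclei
#'
#' The vowel set of the CMU/US-English aligner lexicon; stress digits on
#' phone labels are ignored when matching.
#'
#' @export
arpabet_vowels <- c("AA", "AE", "AH", "AO", "AW", "AY", "EH", "ER", "EY",
                    "IH", "IY", "OW", "OY", "UH", "UW")

#' Is a phone label a vowel?
#'
#' @param label Phone labels (stress digits allowed, case-insensitive).
#' @param vowels Vowel inventory.
#' @return Logical vector.
#' @export
is_vowel_label <- function(label, vowels = arpabet_vowels) {
  toupper(sub("[0-9]+$", "", label)) %in% vowels
}
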