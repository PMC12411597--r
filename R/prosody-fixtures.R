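#' Construct a synthetic prosody fixture with known ground truth
#'
#' Builds an aligned utterance (word and phone interval tiers with a
#' consonant-vowel phone structure) plus a pitch track sampled from an
#' analytic F0 contour, and records the four prosodic measures exactly as
#' constructed, so measurement code can be validated against ground
#' truth. Contour families:
#'
#' * `"constant"`: F0 fixed at `f0_base` (semitone SD is exactly 0);
#' * `"rise"`: linear from `f0_base` to `f0_end` over the utterance
#'   (linear interpolation across unvoiced gaps is exact);
#' * `"peak"`: piecewise linear from `f0_base` up to `f0_peak` at
#'   `peak_time` and back, so the first-word accent is controlled.
#'
#' With `unvoiced_consonants = TRUE` the frames inside consonants are
#' marked unvoiced, exercising the interpolation path; `peak_time` should
#' then lie inside a vowel.
#'
#' @param n_words Number of words.
#' @param vowel_duration,consonant_duration Phone durations (s, > 0).
#' @param contour Contour family.
#' @param f0_base,f0_end,f0_peak,peak_time Contour parameters (Hz, s).
#' @param frame_interval Pitch frame spacing (s).
#' @param unvoiced_consonants Mark consonant frames unvoiced.
#' @param jitter_sd Lognormal jitter SD applied to phone durations (0 =
#'   deterministic timing).
#' @param seed RNG seed for the jitter.
#' @return A list of class `prosody_fixture`: `alignment` (tier tibble),
#'   `pitch` (track tibble), `true_measures` (one-row tibble), `f0_fun`
#'   (the analytic contour).
#' @export
sample_prosody_fixture <- function(n_words = 3L,
                                   vowel_duration = 0.12,
                                   consonant_duration = 0.08,
                                   contour = c("constant", "rise", "peak"),
                                   f0_base = 200, f0_end = 300,
                                   f0_peak = 310, peak_time = NULL,
                                   frame_interval = 0.01,
                                   unvoiced_consonants = FALSE,
                                   jitter_sd = 0, seed = 1L) {
  contour <- match.arg(contour)
  if (vowel_duration <= 0 || consonant_duration <= 0) {
    stop("phone durations must be positive", call. = FALSE)
  }
  vowel_cycle <- c("AA1", "IY0", "UW1", "EH0", "OW1")
  phones <- withr::with_seed(seed, {
    rows <- list()
    t <- 0
    for (w in seq_len(n_words)) {
      for (ph in c("K", vowel_cycle[(w - 1L) %% length(vowel_cycle) + 1L])) {
        d <- if (is_vowel_label(ph)) vowel_duration else consonant_duration
        if (jitter_sd > 0) d <- d * exp(stats::rnorm(1, 0, jitter_sd))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          word = w, label = ph, start = t, end = t + d)
        t <- t + d
      }
    }
    dplyr::bind_rows(rows)
  })
  words <- phones |>
    dplyr::group_by(.data$word) |>
    dplyr::summarise(label = paste0("word", .data$word[1]),
                     start = min(.data$start), end = max(.data$end),
                     .groups = "drop")
  alignment <- dplyr::bind_rows(
    tibble::tibble(tier = "words", label = words$label,
                   start = words$start, end = words$end),
    tibble::tibble(tier = "phones", label = phones$label,
                   start = phones$start, end = phones$end)
  )
  total <- max(phones$end)
  if (is.null(peak_time)) {
    # default: a frame-aligned time inside the first vowel
    v1 <- phones[is_vowel_label(phones$label), ][1, ]
    peak_time <- round((v1$start + v1$end) / 2 / frame_interval) *
      frame_interval
  }
  f0_fun <- switch(contour,
    constant = function(t) rep(f0_base, length(t)),
    rise = function(t) f0_base + (f0_end - f0_base) * t / total,
    peak = function(t) {
      up <- t <= peak_time
      out <- numeric(length(t))
      out[up] <- f0_base + (f0_peak - f0_base) * t[up] / peak_time
      out[!up] <- f0_peak + (f0_base - f0_peak) *
        (t[!up] - peak_time) / (total - peak_time)
      out
    })
  times <- seq(0, total, by = frame_interval)
  in_consonant <- vapply(times, function(t) {
    any(!is_vowel_label(phones$label) & t >= phones$start & t < phones$end)
  }, NA)
  pitch <- tibble::tibble(
    time_s = times,
    f0_hz = f0_fun(times),
    voiced = !(unvoiced_consonants & in_consonant)
  )
  pitch$f0_hz[!pitch$voiced] <- 0

  # ground truth straight from the analytic contour and the constructed
  # intervals, by the definitions of the four measures
  w1 <- words[1, ]
  fw <- f0_fun(times[times >= w1$start & times <= w1$end])
  fall <- f0_fun(times)
  s <- 12 * log2(fall / mean(fall))
  vow <- phones[is_vowel_label(phones$label), ]
  true_measures <- tibble::tibble(
    first_accent_f0_hz = max(fw),
    f0_sd_semitones = stats::sd(s),
    tempo_vowels_per_sec = nrow(vow) / total,
    mean_vowel_duration_s = mean(vow$end - vow$start)
  )
  structure(list(alignment = alignment, pitch = pitch,
                 true_measures = true_measures, f0_fun = f0_fun),
            class = "prosody_fixture")
}

#' @export
print.prosody_fixture <- function(x, ...) {
  cat("<prosody_fixture> ", sum(x$alignment$tier == "words"), " words, ",
      nrow(x$pitch), " pitch frames\n", sep = "")
  print(x$true_measures)
  invisible(x)
}

#' Write a prosody fixture to disk
#'
#' Emits the alignment as a TextGrid and the pitch track as a CSV, the
#' two formats the prosody measures consume.
#'
#' @param fixture A `prosody_fixture`.
#' @param textgrid_path,pitch_path Output paths.
#' @export
write_prosody_fixture <- function(fixture, textgrid_path, pitch_path) {
  write_textgrid(fixture$alignment, textgrid_path)
  write_pitch(fixture$pitch, pitch_path)
  invisible(list(textgrid = textgrid_path, pitch = pitch_path))
}
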