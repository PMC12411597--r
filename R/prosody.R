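#' Preprocess a fundamental-frequency track
#'
#' The standard F0 cleanup applied before any prosodic measure: F0 on
#' unvoiced frames (voiceless consonants, silences) is linearly
#' interpolated between the flanking voiced frames, unvoiced edges are
#' held at the nearest voiced value, and the contour is optionally
#' smoothed with a Savitzky-Golay filter (third-order polynomials over
#' five-sample windows). Timestamps and the voiced flags are never
#' altered; only `f0_hz` changes.
#'
#' @param track A pitch-track tibble (`time_s`, `f0_hz`, `voiced`).
#' @param smooth Apply the Savitzky-Golay filter.
#' @param sg_order,sg_window Filter polynomial order and window length
#'   (samples, odd).
#' @return The track with `f0_hz` replaced by the processed contour.
#' @export
preprocess_f0 <- function(track, smooth = TRUE, sg_order = 3L,
                          sg_window = 5L) {
  stopifnot(all(c("time_s", "f0_hz", "voiced") %in% names(track)))
  if (is.unsorted(track$time_s, strictly = TRUE)) {
    stop("pitch frame times must be strictly increasing", call. = FALSE)
  }
  voiced <- as.logical(track$voiced)
  if (sum(voiced) < max(sg_window, 2L)) {
    stop("need at least ", max(sg_window, 2L),
         " voiced frames to preprocess a contour", call. = FALSE)
  }
  if (any(track$f0_hz[voiced] <= 0, na.rm = TRUE) ||
      any(is.na(track$f0_hz[voiced]))) {
    stop("voiced frames must carry positive f0", call. = FALSE)
  }
  f0 <- stats::approx(track$time_s[voiced], track$f0_hz[voiced],
                      xout = track$time_s, rule = 2)$y
  if (smooth) {
    f0 <- as.numeric(signal::sgolayfilt(f0, p = sg_order, n = sg_window))
  }
  out <- track
  out$f0_hz <- f0
  out
}

frames_in <- function(track, start, end) {
  track$time_s >= start & track$time_s <= end
}

#' Pitch height: F0 of the first word's accent
#'
#' Operationalized as the maximum preprocessed F0 within the first word's
#' time interval (alternative: the F0 at the word's midpoint).
#'
#' @param track A preprocessed pitch-track tibble (see
#'   [preprocess_f0()]).
#' @param alignment An alignment tibble (`tier`, `label`, `start`, `end`)
#'   with a `words` tier; empty labels are ignored.
#' @param method Accent operationalization.
#' @return F0 in Hz.
#' @export
first_accent_f0 <- function(track, alignment,
                            method = c("max", "midpoint")) {
  method <- match.arg(method)
  words <- alignment[alignment$tier == "words" & nzchar(alignment$label), ,
                     drop = FALSE]
  if (nrow(words) == 0) stop("alignment has no word intervals",
                             call. = FALSE)
  w <- words[which.min(words$start), ]
  sel <- frames_in(track, w$start, w$end)
  if (!any(sel)) stop("no pitch frames within the first word",
                      call. = FALSE)
  if (method == "max") {
    max(track$f0_hz[sel])
  } else {
    mid <- (w$start + w$end) / 2
    track$f0_hz[sel][which.min(abs(track$time_s[sel] - mid))]
  }
}

#' Pitch variability in semitones
#'
#' Standard deviation of F0 within the utterance interval, in semitones
#' relative to the arithmetic mean F0 (Hz) of the interval:
#' `s_i = 12 log2(f_i / mean(f))`, sample (n-1) standard deviation of the
#' `s_i`. Invariant under global rescaling of the contour.
#'
#' @param track A preprocessed pitch-track tibble.
#' @param start,end Utterance interval in seconds (defaults: the whole
#'   track).
#' @return Standard deviation in semitones.
#' @export
f0_variability_semitones <- function(track, start = -Inf, end = Inf) {
  f <- track$f0_hz[frames_in(track, start, end)]
  if (length(f) < 2) stop("need at least 2 frames in the interval",
                          call. = FALSE)
  s <- 12 * log2(f / mean(f))
  stats::sd(s)
}

#' Speech tempo in vowels per second
#'
#' Number of vowel phones divided by the utterance duration (first phone
#' start to last phone end), a proxy for syllables per second.
#'
#' @param alignment An alignment tibble with a `phones` tier.
#' @param vowels Vowel inventory (see [is_vowel_label()]).
#' @return Vowels per second.
#' @export
speech_tempo <- function(alignment, vowels = arpabet_vowels) {
  phones <- alignment[alignment$tier == "phones" & nzchar(alignment$label),
                      , drop = FALSE]
  if (nrow(phones) == 0) stop("alignment has no phone intervals",
                              call. = FALSE)
  dur <- max(phones$end) - min(phones$start)
  if (dur <= 0) stop("zero utterance duration", call. = FALSE)
  sum(is_vowel_label(phones$label, vowels)) / dur
}

#' Z-score vowel durations within normalization cells
#'
#' Standardizes each vowel token's duration by the mean and sample SD of
#' its normalization cell; the default cell is the vowel phone label
#' pooled over the whole comparison set, so duration differences between
#' conditions survive while intrinsic phone differences are removed.
#' Cells with fewer than two tokens or zero SD are flagged with a warning
#' and their tokens get `NA`.
#'
#' @param vowel_tokens A tibble with columns `label` and `duration`
#'   (seconds); extra columns (condition, utterance) are carried through.
#' @param cell Column names defining the normalization cell.
#' @return The input tibble with an added `z` column.
#' @export
vowel_duration_z <- function(vowel_tokens, cell = "label") {
  stopifnot(all(c("label", "duration") %in% names(vowel_tokens)),
            all(cell %in% names(vowel_tokens)))
  out <- vowel_tokens |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cell))) |>
    dplyr::mutate(
      .n = dplyr::n(),
      .sd = stats::sd(.data$duration),
      z = (.data$duration - mean(.data$duration)) / .data$.sd
    ) |>
    dplyr::ungroup()
  bad <- out$.n < 2 | is.na(out$.sd) | out$.sd == 0
  if (any(bad)) {
    warning(sum(bad), " vowel token(s) in degenerate normalization cells",
            " excluded (NA)", call. = FALSE)
    out$z[bad] <- NA_real_
  }
  dplyr::select(out, -".n", -".sd")
}

#' All four prosodic measures for one aligned utterance
#'
#' Convenience wrapper: preprocesses the pitch track and returns pitch
#' height (first-word accent F0, Hz), pitch variability (semitone SD),
#' tempo (vowels/s) and the mean vowel duration (seconds; per-token
#' z-scoring across a comparison set is done separately with
#' [vowel_duration_z()]).
#'
#' @param track A raw pitch-track tibble.
#' @param alignment An alignment tibble with `words` and `phones` tiers.
#' @param smooth Savitzky-Golay smoothing on the contour.
#' @param vowels Vowel inventory.
#' @return A one-row tibble: `first_accent_f0_hz`, `f0_sd_semitones`,
#'   `tempo_vowels_per_sec`, `mean_vowel_duration_s`.
#' @export
prosody_measures <- function(track, alignment, smooth = TRUE,
                             vowels = arpabet_vowels) {
  pp <- preprocess_f0(track, smooth = smooth)
  phones <- alignment[alignment$tier == "phones" & nzchar(alignment$label),
                      , drop = FALSE]
  vow <- phones[is_vowel_label(phones$label, vowels), , drop = FALSE]
  tibble::tibble(
    first_accent_f0_hz = first_accent_f0(pp, alignment),
    f0_sd_semitones = f0_variability_semitones(
      pp, min(phones$start), max(phones$end)),
    tempo_vowels_per_sec = speech_tempo(alignment, vowels),
    mean_vowel_duration_s = if (nrow(vow)) {
      mean(vow$end - vow$start)
    } else {
      NA_real_
    }
  )
}

#' Condition-level prosody report
#'
#' Summarizes per-utterance prosodic measures by condition and runs the
#' distribution comparisons: Shapiro-Wilk normality per condition and
#' measure, and rank-based pairwise tests between conditions (Wilcoxon
#' signed-rank when the two conditions have equal sample sizes and
#' `paired = TRUE`, otherwise the unpaired rank-sum test, noted in the
#' output). Conditions with fewer than three values for a measure are
#' skipped with a warning.
#'
#' @param measures A tibble with a `condition` column plus one column per
#'   prosodic measure (e.g. rows of [prosody_measures()] outputs).
#' @param paired Prefer the paired signed-rank test when group sizes
#'   match.
#' @return A list of tibbles: `summary` (n, mean, sd, shapiro_p per
#'   condition x measure) and `pairwise` (test, statistic, p per measure
#'   and condition pair).
#' @export
prosody_report <- function(measures, paired = TRUE) {
  stopifnot("condition" %in% names(measures))
  long <- measures |>
    tidyr::pivot_longer(-"condition", names_to = "measure",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  counts <- long |>
    dplyr::count(.data$condition, .data$measure)
  small <- counts[counts$n < 3, ]
  if (nrow(small) > 0) {
    warning("skipping condition(s) with < 3 values: ",
            paste(unique(small$condition), collapse = ", "),
            call. = FALSE)
    long <- dplyr::anti_join(long, small[c("condition", "measure")],
                             by = c("condition", "measure"))
  }
  summary <- long |>
    dplyr::group_by(.data$condition, .data$measure) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$value),
      sd = stats::sd(.data$value),
      shapiro_p = tryCatch(
        stats::shapiro.test(.data$value)$p.value,
        error = function(e) NA_real_),
      .groups = "drop"
    )
  conds <- unique(long$condition)
  pairs <- if (length(conds) >= 2) utils::combn(conds, 2, simplify = FALSE)
    else list()
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(unique(long$measure), function(m) {
      x <- long$value[long$condition == pr[1] & long$measure == m]
      y <- long$value[long$condition == pr[2] & long$measure == m]
      if (length(x) < 3 || length(y) < 3) return(NULL)
      use_paired <- paired && length(x) == length(y)
      if (use_paired && all(x == y)) {
        # all paired differences are zero: no evidence of any difference
        stat <- 0
        p <- 1
      } else {
        wt <- suppressWarnings(
          stats::wilcox.test(x, y, paired = use_paired, exact = FALSE))
        stat <- unname(wt$statistic)
        p <- wt$p.value
      }
      tibble::tibble(
        measure = m, condition_a = pr[1], condition_b = pr[2],
        test = if (use_paired) "wilcoxon_signed_rank" else
          "wilcoxon_rank_sum",
        statistic = stat, p_value = p)
    })
  })
  list(summary = summary, pairwise = pairwise)
}
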