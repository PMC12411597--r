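#' Subsampled distribution of a metric
#'
#' Evaluates a metric on `n_resamples` equal-size random subsamples drawn
#' with replacement, the protocol used throughout the evaluation battery
#' so that size-sensitive measures (TTR in particular) are compared at a
#' fixed sample size. The sampling unit is either words (rows of a token
#' table; default unit size 10,000 for lexical richness) or utterances
#' (default unit size 1,000 for syntactic complexity).
#'
#' @param data A token table (`unit = "words"`) or a parsed utterance
#'   table with `utt_id` (`unit = "utterances"`).
#' @param metric Function mapping the resampled table to a named numeric
#'   vector or one-row data frame, e.g. [lexical_profile()] or
#'   [syntactic_profile()].
#' @param n_resamples Number of resamples.
#' @param unit Sampling unit.
#' @param unit_size Units per resample.
#' @param seed RNG seed.
#' @return A `metric_distribution` tibble: `.resample` plus one column per
#'   metric component.
#' @export
subsampled_distribution <- function(data, metric, n_resamples = 100L,
                                    unit = c("words", "utterances"),
                                    unit_size = NULL, seed = 1L) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(data), nrow(data) > 0, is.function(metric))
  if (is.null(unit_size)) {
    unit_size <- if (unit == "words") 10000L else 1000L
  }
  if (unit == "utterances") {
    stopifnot("utt_id" %in% names(data))
    idx_by_utt <- split(seq_len(nrow(data)), data$utt_id)
  }
  withr::with_seed(seed, {
    rows <- purrr::map(seq_len(n_resamples), function(r) {
      sampled <- if (unit == "words") {
        data[sample.int(nrow(data), unit_size, replace = TRUE), ,
             drop = FALSE]
      } else {
        pick <- sample.int(length(idx_by_utt), unit_size, replace = TRUE)
        take <- idx_by_utt[pick]
        out <- data[unlist(take, use.names = FALSE), , drop = FALSE]
        # re-key duplicates so repeated utterances stay distinct units
        out$utt_id <- rep(seq_along(take), lengths(take))
        out
      }
      val <- metric(sampled)
      out <- tibble::as_tibble(as.list(unlist(val)))
      out$.resample <- r
      out
    })
    out <- dplyr::bind_rows(rows)
    out <- dplyr::relocate(out, ".resample")
    class(out) <- c("metric_distribution", class(out))
    out
  })
}

#' Effect size between two resample distributions
#'
#' Cohen's d (absolute mean difference over the pooled sample standard
#' deviation of the two resample distributions), the relative absolute
#' difference of the means in percent (denominator: the reference side
#' `b`), and a two-tailed Student t-test.
#'
#' @param a,b Numeric vectors of per-resample metric values; `b` is the
#'   reference (original-data) distribution.
#' @return A one-row tibble: `cohens_d`, `relative_abs_difference_percent`,
#'   `t_statistic`, `p_value`, `mean_a`, `mean_b`. `cohens_d` is `NA` (with
#'   a warning) when the pooled SD is zero.
#' @export
effect_size <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a)
  nb <- length(b)
  pooled <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
                   (na + nb - 2))
  d <- if (pooled > 0) abs(mean(a) - mean(b)) / pooled else {
    warning("pooled SD is zero; Cohen's d undefined", call. = FALSE)
    NA_real_
  }
  tt <- if (pooled > 0) {
    stats::t.test(a, b, var.equal = TRUE)
  } else {
    list(statistic = c(t = NA_real_),
         p.value = if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tibble::tibble(
    cohens_d = d,
    relative_abs_difference_percent =
      100 * abs(mean(a) - mean(b)) / abs(mean(b)),
    t_statistic = unname(tt$statistic),
    p_value = tt$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}
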