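#' Age-trend comparison report between generated and reference corpora
#'
#' Takes per-bin resample distributions for two corpus sources and
#' produces the standard comparison battery: per-(measure, bin) effect
#' sizes, the per-measure summary averaged across bins (mean Cohen's d and
#' mean relative absolute difference), the per-bin summary averaged across
#' measures, and second-order polynomial trend fits of each measure
#' against age for each source.
#'
#' @param distributions A long tibble with columns `source` (two levels,
#'   e.g. "generated" and "reference"), `age_bin` (months), `metric`
#'   (measure name) and `value` (one row per resample).
#' @param reference Which level of `source` is the reference side (the
#'   denominator of relative differences).
#' @return An object of class `age_trend_report`: a list of tibbles
#'   `by_measure_bin`, `measure_summary` (Cohen's d and relative
#'   difference averaged over bins), `bin_summary` (averaged over
#'   measures), and `trend_fits` (quadratic coefficients per measure and
#'   source).
#' @export
age_trend_report <- function(distributions, reference = "reference") {
  needed <- c("source", "age_bin", "metric", "value")
  stopifnot(all(needed %in% names(distributions)))
  src <- unique(distributions$source)
  if (length(src) != 2 || !reference %in% src) {
    stop("`distributions` must contain exactly two sources including `",
         reference, "`", call. = FALSE)
  }
  other <- setdiff(src, reference)
  bins_by_src <- distributions |>
    dplyr::distinct(.data$source, .data$age_bin, .data$metric)
  a_keys <- bins_by_src[bins_by_src$source == other, -1]
  b_keys <- bins_by_src[bins_by_src$source == reference, -1]
  if (!identical(dplyr::arrange(a_keys, .data$age_bin, .data$metric),
                 dplyr::arrange(b_keys, .data$age_bin, .data$metric))) {
    stop("sources cover different (age_bin, metric) combinations",
         call. = FALSE)
  }

  by_measure_bin <- distributions |>
    tidyr::pivot_wider(names_from = "source", values_from = "value",
                       values_fn = list) |>
    dplyr::rowwise() |>
    dplyr::mutate(effect_size(.data[[other]], .data[[reference]])) |>
    dplyr::ungroup() |>
    dplyr::select(-dplyr::all_of(src))

  measure_summary <- by_measure_bin |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      cohens_d = mean(.data$cohens_d),
      relative_abs_difference_percent =
        mean(.data$relative_abs_difference_percent),
      .groups = "drop"
    )
  bin_summary <- by_measure_bin |>
    dplyr::group_by(.data$age_bin) |>
    dplyr::summarise(
      cohens_d = mean(.data$cohens_d),
      relative_abs_difference_percent =
        mean(.data$relative_abs_difference_percent),
      .groups = "drop"
    )

  trend_fits <- distributions |>
    dplyr::group_by(.data$source, .data$metric, .data$age_bin) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$source, .data$metric) |>
    dplyr::group_modify(function(g, key) {
      fit <- stats::lm(value ~ stats::poly(age_bin, 2, raw = TRUE), data = g)
      tibble::tibble(intercept = stats::coef(fit)[1],
                     linear = stats::coef(fit)[2],
                     quadratic = stats::coef(fit)[3])
    }) |>
    dplyr::ungroup()

  structure(list(by_measure_bin = by_measure_bin,
                 measure_summary = measure_summary,
                 bin_summary = bin_summary,
                 trend_fits = trend_fits,
                 reference = reference, generated = other),
            class = "age_trend_report")
}

#' @export
print.age_trend_report <- function(x, ...) {
  cat("<age_trend_report> ", x$generated, " vs ", x$reference, "\n",
      sep = "")
  cat("\nPer-measure summary (mean over bins):\n")
  print(x$measure_summary, n = Inf)
  cat("\nPer-bin summary (mean over measures):\n")
  print(x$bin_summary, n = Inf)
  invisible(x)
}

#' Plot an age-trend report
#'
#' Per-bin resample means by source with the quadratic trend fit overlaid,
#' one facet per measure.
#'
#' @param object An `age_trend_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_trend_report <- function(object, ...) {
  means <- object$by_measure_bin |>
    tidyr::pivot_longer(c("mean_a", "mean_b"),
                        names_to = "side", values_to = "mean_value") |>
    dplyr::mutate(source = ifelse(.data$side == "mean_a",
                                  object$generated, object$reference))
  ggplot2::ggplot(means,
                  ggplot2::aes(.data$age_bin, .data$mean_value,
                               colour = .data$source)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(formula = y ~ poly(x, 2), method = "lm",
                         se = FALSE, linetype = "dashed", linewidth = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "age (months)", y = "resample mean",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
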