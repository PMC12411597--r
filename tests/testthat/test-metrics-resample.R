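test_that("resampling defaults, determinism and degenerate corpora behave", {
  spec <- cds_trend_preset("flat", seed = 2)
  gold <- sample_corpus(spec, 24, n_utterances = 400, seed = 2)
  d1 <- subsampled_distribution(gold, lexical_profile, n_resamples = 10L,
                                unit = "words", unit_size = 500L, seed = 5)
  expect_s3_class(d1, "metric_distribution")
  expect_equal(nrow(d1), 10L)
  d2 <- subsampled_distribution(gold, lexical_profile, n_resamples = 10L,
                                unit = "words", unit_size = 500L, seed = 5)
  expect_identical(d1, d2)
  # one repeated utterance -> zero variance across resamples
  one <- gold[gold$utt_id == 1, ]
  dd <- subsampled_distribution(one, syntactic_profile, n_resamples = 8L,
                                unit = "utterances", unit_size = 20L,
                                seed = 1)
  expect_equal(var(dd$mean_utt_len), 0)
  expect_equal(var(dd$mean_tree_height), 0)
})

test_that("resampled mean utterance length is location-equivariant", {
  spec <- cds_trend_preset("flat", seed = 4)
  gold <- sample_corpus(spec, 24, n_utterances = 300, seed = 4)
  # append one root-attached word to every utterance: all lengths shift by 1
  extra <- gold |>
    dplyr::group_by(.data$utt_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::mutate(position = .data$position + 1L, form = "adv1",
                  lemma = "adv1", upos = "ADV", deprel = "advmod")
  root_pos <- gold |>
    dplyr::group_by(.data$utt_id) |>
    dplyr::summarise(r = .data$position[.data$head == 0], .groups = "drop")
  extra$head <- root_pos$r[match(extra$utt_id, root_pos$utt_id)]
  shifted <- dplyr::bind_rows(gold, extra) |>
    dplyr::arrange(.data$utt_id, .data$position)
  m <- function(x) syntactic_profile(x)["mean_utt_len"]
  d0 <- subsampled_distribution(gold, m, n_resamples = 15L,
                                unit = "utterances", unit_size = 50L,
                                seed = 9)
  d1 <- subsampled_distribution(shifted, m, n_resamples = 15L,
                                unit = "utterances", unit_size = 50L,
                                seed = 9)
  expect_equal(d1$mean_utt_len, d0$mean_utt_len + 1)
})

test_that("effect size matches hand-computed cases", {
  x <- c(0.8, 1.2, 1.0, 1.0)
  same <- effect_size(x, x)
  expect_equal(same$cohens_d, 0)
  expect_equal(same$relative_abs_difference_percent, 0)
  # means 1 and 0, both sample SD 1, equal n -> pooled SD 1 -> d = 1
  a <- c(0, 1, 2)  # mean 1, sd 1
  b <- c(-1, 0, 1) # mean 0, sd 1
  es <- effect_size(a, b)
  expect_equal(es$cohens_d, 1.0)
  expect_equal(es$t_statistic,
               unname(t.test(a, b, var.equal = TRUE)$statistic))
  expect_equal(es$p_value, t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("Cohen's d is symmetric and scale-invariant; relative difference is not", {
  set.seed(8)
  a <- rnorm(40, 2)
  b <- rnorm(40, 3)
  es_ab <- effect_size(a, b)
  es_ba <- effect_size(b, a)
  expect_equal(es_ab$cohens_d, es_ba$cohens_d)
  expect_false(isTRUE(all.equal(es_ab$relative_abs_difference_percent,
                                es_ba$relative_abs_difference_percent)))
  es_scaled <- effect_size(10 * a, 10 * b)
  expect_equal(es_scaled$cohens_d, es_ab$cohens_d)
  expect_warning(es0 <- effect_size(rep(1, 5), rep(1, 5)), "pooled SD")
  expect_true(is.na(es0$cohens_d))
})
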