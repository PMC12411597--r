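# tiny vocabulary: pieces ".", "a", "b" (ids 0, 1, 2 after sorting rules)
ab_vocab <- function() train_subword_vocab(c("a b", "b a"), size = 3L)

onehot_stub <- function(emission, v = 3L) {
  # emits `emission` (0-based ids) by generation step, ignoring the seed
  force(emission)
  n_fed <- 0L
  function(ids, age) {
    p <- rep(0, v)
    step <- length(ids)  # called with seed(1) + generated so far
    p[emission[step] + 1L] <- 1
    p
  }
}

test_that("seed prompts are contiguous uniform slices of the stream", {
  stream <- sample.int(50L, 4000L, replace = TRUE)
  withr::with_seed(1, {
    lens <- integer(10000)
    for (i in seq_along(lens)) {
      s <- sample_seed(stream)
      lens[i] <- length(s)
      if (i <= 200) {
        # verbatim contiguity: the slice occurs in the stream
        hay <- paste(stream, collapse = ",")
        expect_true(grepl(paste(s, collapse = ","), hay, fixed = TRUE))
      }
    }
    freq <- tabulate(lens, 4) / length(lens)
    expect_true(all(abs(freq - 0.25) < 0.02))
  })
  withr::with_seed(7, s1 <- sample_seed(stream))
  withr::with_seed(7, s2 <- sample_seed(stream))
  expect_identical(s1, s2)
  expect_error(sample_seed(1:2), "shorter")
})

test_that("top-k = 1 is deterministic argmax; ties break to the lower id", {
  p <- c(0.1, 0.4, 0.4, 0.1)
  withr::with_seed(1, {
    for (i in 1:20) expect_equal(sample_next(p, top_k = 1L), 1L)
  })
  # with k = 3 the tie at the 3rd slot keeps id 0 (lower) over id 3
  withr::with_seed(2, {
    draws <- replicate(2000, sample_next(p, top_k = 3L))
    expect_true(all(draws %in% c(0L, 1L, 2L)))
  })
})

test_that("sampled ids always lie in the top k of the distribution", {
  withr::with_seed(3, {
    p <- runif(40)
    p <- p / sum(p)
    top5 <- order(-p)[1:5] - 1L
    draws <- replicate(10000, sample_next(p, top_k = 5L))
    expect_true(all(draws %in% top5))
  })
})

test_that("empirical sampling law matches the masked renormalized distribution (chi-square)", {
  withr::with_seed(4, {
    p <- runif(10)
    p <- p / sum(p)
    # full-support temperature-1 sampling follows p itself
    draws <- replicate(1e5, sample_next(p, top_k = 10L))
    tab <- tabulate(draws + 1L, 10)
    expect_gt(chisq.test(tab, p = p)$p.value, 0.01)
    # truncated + temperature-scaled sampling follows the reference law
    ref <- sample_next_reference_dist(p, top_k = 4L, temperature = 2)
    draws2 <- replicate(1e5, sample_next(p, top_k = 4L, temperature = 2))
    tab2 <- tabulate(draws2 + 1L, 10)
    expect_gt(chisq.test(tab2[ref > 0], p = ref[ref > 0])$p.value, 0.01)
  })
  expect_error(sample_next(c(1, 0, 0), top_k = 1L, temperature = 1) -> x,
               NA)
  expect_error(sample_next(c(0, 0, 1e-300^2), top_k = 2L), "mass")
})

test_that("discard rules reproduce the hand-traced stub generations", {
  vocab <- ab_vocab()
  stop_id <- vocab$end_of_utterance_id
  a_id <- wp_encode(vocab, "a", append_stop = FALSE)[[1]]
  b_id <- wp_encode(vocab, "b", append_stop = FALSE)[[1]]
  cfg <- generation_config(top_k = 3L, sample_len_tokens = 8L,
                           seed_len_range = c(1L, 1L))
  # stub emits: a a . b b b . after the 1-token seed
  emission <- c(a_id, a_id, stop_id, b_id, b_id, b_id, stop_id)
  stub <- function(ids, age) {
    p <- rep(0, 3)
    p[emission[length(ids)] + 1L] <- 1
    p
  }
  s <- withr::with_seed(5,
    generate_sample(stub, vocab, 24, cfg, train_stream = rep(a_id, 10)))
  expect_equal(s$utterances, "b b b")
  expect_equal(length(s$raw_token_ids), 8L)
  expect_equal(s$seed_tokens, a_id)

  # a model that only ever emits the full stop retains nothing
  stop_stub <- function(ids, age) {
    p <- rep(0, 3)
    p[stop_id + 1L] <- 1
    p
  }
  s2 <- withr::with_seed(5,
    generate_sample(stop_stub, vocab, 24, cfg, rep(a_id, 10)))
  expect_length(s2$utterances, 0L)
})

test_that("every retained utterance ends at a full stop and excludes the seed", {
  vocab <- ab_vocab()
  stop_id <- vocab$end_of_utterance_id
  ids01 <- setdiff(0:2, stop_id)
  random_stub <- function(ids, age) {
    p <- runif(3) + 0.1
    p / sum(p)
  }
  cfg <- generation_config(top_k = 3L, sample_len_tokens = 30L)
  stream <- rep(ids01, 10)
  for (i in 1:25) {
    s <- withr::with_seed(100 + i,
      generate_sample(random_stub, vocab, 12, cfg, stream))
    expect_lte(length(s$raw_token_ids), 30L)
    if (length(s$utterances)) {
      # re-encoding each retained utterance ends with the stop token
      for (u in s$utterances) {
        enc <- wp_encode(vocab, u)[[1]]
        expect_equal(enc[length(enc)], stop_id)
      }
      n_seed <- length(s$seed_tokens)
      segs <- cdsgen:::segment_ids(s$raw_token_ids, stop_id)
      ends <- cumsum(lengths(segs$complete))
      starts <- c(1L, head(ends, -1) + 1L)
      kept <- which(starts > n_seed)
      expect_length(s$utterances,
                    sum(vapply(segs$complete[kept],
                               function(x) length(x) > 1L, NA)))
    }
  }
})

test_that("corpus generation is deterministic, schema-valid, and counts words", {
  vocab <- ab_vocab()
  random_stub <- function(ids, age) {
    p <- runif(3) + 0.1
    p / sum(p)
  }
  cfg <- generation_config(top_k = 3L, sample_len_tokens = 15L,
                           n_samples_per_age = 20L, rng_seed = 11L)
  stream <- rep(0:2, 20)
  c1 <- generate_age_corpus(random_stub, vocab, c(6, 24), cfg, stream,
                            quiet = TRUE)
  c2 <- generate_age_corpus(random_stub, vocab, c(6, 24), cfg, stream,
                            quiet = TRUE)
  expect_identical(as.data.frame(c1), as.data.frame(c2))
  expect_setequal(unique(c1$child_age_months), c(6, 24))
  expect_true(all(c1$sample_index %in% 1:20))
  wc <- attr(c1, "word_counts")
  expect_equal(nrow(wc), 2L)
  expect_equal(wc$n_words[wc$age == 6],
               sum(lengths(strsplit(c1$utterance[c1$child_age_months == 6],
                                    " "))))
  # different master seed changes the corpus
  cfg2 <- generation_config(top_k = 3L, sample_len_tokens = 15L,
                            n_samples_per_age = 20L, rng_seed = 12L)
  c3 <- generate_age_corpus(random_stub, vocab, c(6, 24), cfg2, stream,
                            quiet = TRUE)
  expect_false(identical(c1$utterance, c3$utterance))
})

test_that("same-bin seeding picks the per-age stream when available", {
  vocab <- ab_vocab()
  cfg <- generation_config(top_k = 1L, sample_len_tokens = 5L,
                           seed_len_range = c(2L, 2L),
                           n_samples_per_age = 5L, rng_seed = 3L)
  a_id <- wp_encode(vocab, "a", append_stop = FALSE)[[1]]
  b_id <- wp_encode(vocab, "b", append_stop = FALSE)[[1]]
  stop_stub <- function(ids, age) {
    p <- rep(0, 3)
    p[vocab$end_of_utterance_id + 1L] <- 1
    p
  }
  streams <- list("6" = rep(a_id, 10L), "24" = rep(b_id, 10L))
  out <- generate_age_corpus(stop_stub, vocab, c(6, 24), cfg, streams,
                             quiet = TRUE)
  # no retained utterances, but generation must have used per-age seeds:
  # rerun one sample by hand and check its seed came from the right stream
  s <- withr::with_seed(
    withr::with_seed((3L * 1009L + 101L) %% 2147483111L,
                     sample.int(2147483111L, 5L))[1],
    generate_sample(stop_stub, vocab, 6, cfg, streams[["6"]]))
  expect_true(all(s$seed_tokens == a_id))
})
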