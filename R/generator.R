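#' Stochastic generation settings
#'
#' Defaults follow the working generation protocol: temperature 1 (the
#' unmodified posterior), top-500 truncation, 60-token samples, seed
#' prompts of 1-4 contiguous training tokens, 2,000 samples per age.
#'
#' @param temperature Softmax temperature (> 0).
#' @param top_k Number of most likely tokens kept (>= 1).
#' @param sample_len_tokens Total tokens per sample, seed included.
#' @param seed_len_range Inclusive range of seed prompt lengths.
#' @param n_samples_per_age Samples generated per conditioning age.
#' @param rng_seed Master seed; per-age and per-sample sub-seeds derive
#'   from it.
#' @return An object of class `generation_config`.
#' @export
generation_config <- function(temperature = 1, top_k = 500L,
                              sample_len_tokens = 60L,
                              seed_len_range = c(1L, 4L),
                              n_samples_per_age = 2000L, rng_seed = 1L) {
  stopifnot(temperature > 0, top_k >= 1, sample_len_tokens >= 2,
            length(seed_len_range) == 2, seed_len_range[1] >= 1,
            seed_len_range[2] >= seed_len_range[1])
  structure(list(temperature = temperature, top_k = as.integer(top_k),
                 sample_len_tokens = as.integer(sample_len_tokens),
                 seed_len_range = as.integer(seed_len_range),
                 n_samples_per_age = as.integer(n_samples_per_age),
                 rng_seed = as.integer(rng_seed)),
            class = "generation_config")
}

#' Draw a seed prompt from a training token stream
#'
#' A contiguous slice whose length is uniform on `seed_len_range` and
#' whose start position is uniform over the stream. Uses the current RNG
#' state; wrap in [withr::with_seed()] for determinism.
#'
#' @param stream Integer vector of training token ids.
#' @param seed_len_range Inclusive length range.
#' @return Integer vector of seed token ids.
#' @export
sample_seed <- function(stream, seed_len_range = c(1L, 4L)) {
  n <- length(stream)
  if (n < seed_len_range[2]) {
    stop("training stream shorter than the maximum seed length",
         call. = FALSE)
  }
  len <- sample(seq.int(seed_len_range[1], seed_len_range[2]), 1L)
  start <- sample.int(n - len + 1L, 1L)
  stream[start:(start + len - 1L)]
}

#' Sample the next token from a distribution
#'
#' Top-k truncated, temperature-scaled sampling: all but the `top_k`
#' largest probabilities are zeroed (ties at the k-th value broken
#' towards the lower token id), the surviving probabilities are raised to
#' `1/temperature` (equivalent to dividing the logits by the
#' temperature), renormalized, and one token id is drawn. Uses the
#' current RNG state.
#'
#' @param distribution Probability vector over token ids `0..V-1`.
#' @param top_k,temperature See [generation_config()].
#' @return A 0-based token id.
#' @export
sample_next <- function(distribution, top_k = 500L, temperature = 1) {
  v <- length(distribution)
  ord <- order(-distribution, seq_len(v))
  keep <- ord[seq_len(min(top_k, v))]
  w <- distribution[keep]^(1 / temperature)
  if (!any(w > 0)) {
    stop("no probability mass left after top-k masking", call. = FALSE)
  }
  if (length(keep) == 1L) return(keep - 1L)
  keep[sample.int(length(keep), 1L, prob = w)] - 1L
}

# next-token distribution; `model` is an age_lm or, for stub models in
# tests, a function(ids_0based, age) -> probability vector
next_token_dist <- function(model, ids, age) {
  if (is.function(model)) return(model(ids, age))
  ctx_len <- model$config$seq_len
  if (length(ids) > ctx_len) ids <- ids[(length(ids) - ctx_len + 1L):length(ids)]
  p <- age_lm_forward(model, ids, age)
  p[nrow(p), ]
}

segment_ids <- function(ids, stop_id) {
  segs <- list()
  cur <- integer(0)
  for (id in ids) {
    cur <- c(cur, id)
    if (id == stop_id) {
      segs[[length(segs) + 1L]] <- cur
      cur <- integer(0)
    }
  }
  list(complete = segs, trailing = cur)
}

#' Generate one text sample from a model
#'
#' Token-by-token generation from a 1-4 token seed prompt drawn from the
#' training stream, continued until `sample_len_tokens` total tokens
#' (seed included). Post-processing applies the two discard rules: every
#' utterance containing seed tokens is dropped, and the trailing
#' utterance is dropped unless it ends in a full stop. The remaining
#' full-stop-delimited token segments are decoded to word strings.
#' Uses the current RNG state; wrap in [withr::with_seed()] for
#' determinism.
#'
#' @param model An `age_lm` (or a stub function `(ids, age) -> probability
#'   vector`).
#' @param vocab The `wordpiece_vocab` matching the model.
#' @param age Conditioning age in months.
#' @param config A [generation_config()].
#' @param train_stream Integer token stream seeds are drawn from.
#' @return A list of class `generated_sample`: `seed_tokens`,
#'   `raw_token_ids` (seed + generated, length <= `sample_len_tokens`),
#'   `utterances` (character; possibly empty), `age`.
#' @export
generate_sample <- function(model, vocab, age, config, train_stream) {
  stopifnot(inherits(config, "generation_config"),
            inherits(vocab, "wordpiece_vocab"))
  stop_id <- vocab$end_of_utterance_id
  seed_ids <- sample_seed(train_stream, config$seed_len_range)
  ids <- seed_ids
  while (length(ids) < config$sample_len_tokens) {
    p <- next_token_dist(model, ids, age)
    ids <- c(ids, sample_next(p, config$top_k, config$temperature))
  }
  segs <- segment_ids(ids, stop_id)
  n_seed <- length(seed_ids)
  # utterances whose token span overlaps the seed are discarded
  ends <- cumsum(lengths(segs$complete))
  starts <- c(1L, utils::head(ends, -1) + 1L)
  keep <- segs$complete[starts > n_seed]
  utterances <- vapply(keep, function(s) {
    wp_decode(vocab, s, drop_incomplete = FALSE)
  }, "")
  utterances <- utterances[nzchar(utterances)]
  structure(list(seed_tokens = seed_ids, raw_token_ids = ids,
                 utterances = utterances, age = age),
            class = "generated_sample")
}

#' Generate an age-conditioned corpus
#'
#' Draws `n_samples_per_age` samples for every requested age. Seeds come
#' from the same-age training stream when `train_streams` is a named
#' list keyed by age bin, else from the single stream supplied.
#' Per-sample sub-seeds are derived deterministically from
#' `config$rng_seed`, so the whole corpus is reproducible; the sub-seed
#' is recorded on every row.
#'
#' @param model An `age_lm` (or stub function).
#' @param vocab The matching `wordpiece_vocab`.
#' @param ages Conditioning ages in months.
#' @param config A [generation_config()].
#' @param train_streams Integer vector, or named list of integer vectors
#'   keyed by age (e.g. `"6"`).
#' @param quiet Suppress the per-age word-count message.
#' @return A corpus tibble (`utterance`, `speaker_role = "model"`,
#'   `child_age_months`, `corpus_id = "generated"`) with extra columns
#'   `sample_index` and `sub_seed`; the per-age word counts (full stops
#'   excluded) are attached as attribute `word_counts`.
#' @export
generate_age_corpus <- function(model, vocab, ages, config,
                                train_streams, quiet = FALSE) {
  rows <- list()
  counts <- list()
  for (ai in seq_along(ages)) {
    age <- ages[ai]
    stream <- if (is.list(train_streams)) {
      train_streams[[as.character(age)]] %||%
        unlist(train_streams, use.names = FALSE)
    } else {
      train_streams
    }
    age_seed <- (config$rng_seed * 1009L + 101L * ai) %% 2147483111L
    sub_seeds <- withr::with_seed(age_seed,
      sample.int(2147483111L, config$n_samples_per_age))
    samples <- lapply(seq_len(config$n_samples_per_age), function(i) {
      withr::with_seed(sub_seeds[i],
        generate_sample(model, vocab, age, config, stream))
    })
    utts <- purrr::map(samples, "utterances")
    n_utts <- lengths(utts)
    rows[[ai]] <- tibble::tibble(
      utterance = unlist(utts, use.names = FALSE) %||% character(0),
      speaker_role = "model",
      child_age_months = as.numeric(age),
      corpus_id = "generated",
      sample_index = rep(seq_along(utts), n_utts),
      sub_seed = rep(sub_seeds, n_utts)
    )
    n_words <- sum(lengths(strsplit(rows[[ai]]$utterance, " ",
                                    fixed = TRUE)))
    counts[[ai]] <- tibble::tibble(age = age, n_words = n_words)
    if (!quiet) {
      message("age ", age, ": ", config$n_samples_per_age, " samples, ",
              n_words, " words")
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "word_counts") <- dplyr::bind_rows(counts)
  out
}
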