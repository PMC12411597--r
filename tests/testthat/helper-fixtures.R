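# Shared fixtures: tiny corpora and specs built in code.

tiny_corpus <- function() {
  tibble::tibble(
    utterance = c("look at the doggy", "you want the ball",
                  "where is it", "no", "give me the ball now",
                  "the doggy wants the ball"),
    speaker_role = "mother",
    child_age_months = c(10.2, 12.0, 24.5, 30.0, 57.0, 57.9),
    corpus_id = "toy"
  )
}

# corpus large enough to train a small subword vocabulary on
vocab_corpus <- function(n = 400, seed = 42) {
  spec <- cds_trend_preset("flat", seed = seed)
  gold_to_corpus(sample_corpus(spec, age = 24, n_utterances = n, seed = seed))
}
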