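# Independent brute-force oracles used to cross-check the implementations.

# is `needle` (word vector) a contiguous subsequence of any single
# training utterance? plain O(n*m) window scan over word vectors
novelty_oracle <- function(generated, training) {
  train_words <- strsplit(training$utterance, " ", fixed = TRUE)
  vapply(strsplit(generated$utterance, " ", fixed = TRUE), function(g) {
    k <- length(g)
    for (t in train_words) {
      n <- length(t)
      if (n < k) next
      for (s in seq_len(n - k + 1L)) {
        if (all(t[s:(s + k - 1L)] == g)) return(FALSE)  # attested
      }
    }
    TRUE  # novel
  }, NA)
}

# top-k + temperature reference: masked, scaled, renormalized distribution
sample_next_reference_dist <- function(p, top_k, temperature) {
  ord <- order(-p, seq_along(p))
  keep <- ord[seq_len(min(top_k, length(p)))]
  out <- numeric(length(p))
  out[keep] <- p[keep]^(1 / temperature)
  out / sum(out)
}

random_small_corpus <- function(n_utts, vocab = letters[1:5], max_len = 5) {
  tibble::tibble(
    utterance = vapply(seq_len(n_utts), function(i) {
      paste(sample(vocab, sample.int(max_len, 1), replace = TRUE),
            collapse = " ")
    }, ""),
    speaker_role = "mother", child_age_months = 24, corpus_id = "rnd"
  )
}
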