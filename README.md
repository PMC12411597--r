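# cdsgen

Age-conditioned generation and evaluation of child-directed speech (CDS)
transcripts, in R.

Caregivers adapt their speech to a child's developmental level: between
roughly 6 and 48 months of age, utterances grow from about four towards six
words, vocabulary becomes richer, and syntax more complex. `cdsgen` is for
researchers in computational language acquisition who want to *simulate*
such input at scale: it trains a small decoder-only transformer language
model conditioned on child age over CHILDES-style transcript exports,
samples new age-appropriate transcripts from it, and measures how closely
the generated corpora track real (or gold synthetic) corpora across a
battery of lexical, syntactic, novelty and prosodic statistics.

## What is inside

**Corpus tooling** — transcript normalization (lower-case, punctuation
stripped, apostrophes kept, `xxx`/`yyy`/`www` incomprehensible-speech
markers dropped), 3-month age binning with centers 3, 6, ..., 84 months,
JSONL corpus I/O, a WordPiece subword tokenizer (pieces never cross word
boundaries; exact round-trip), and fixed-length training-sample
construction with a held-out validation bin.

**The model** — a GPT-2-style decoder-only transformer: token + learned
positional embeddings combined by summation; the scalar age *a* (months)
is mapped through a one-hidden-layer ReLU encoder to an embedding that is
concatenated *in front of* the token sequence (no positional embedding, no
loss at that position). With causal masking, position *t* predicts token
*t + 1*; training minimizes the mean token cross-entropy

&nbsp;&nbsp;&nbsp;&nbsp;L = −(1/N) Σ log p(w_{t+1} | w_{≤t}, a)

with Adam, minibatches, and validation-loss early stopping. The forward
and backward passes are implemented in base R matrix code and verified
against finite-difference gradients in the test suite.

**Generation** — seed prompts of 1–4 contiguous tokens drawn from the
training stream, token-by-token top-k (default 500) temperature-1
sampling to 60 tokens, then two discard rules: the utterance containing
the seed, and any trailing utterance not closed by a full stop.

**Evaluation** — type-token ratio (TTR) of lemmas, per-POS rates and
TTRs (CONJ pooling CCONJ+SCONJ), base-2 Jensen–Shannon lexical
divergence, dependency-tree syntactic complexity (utterance length,
dependent-clause rate, tree height, dependents per word, dependency
distance), pluggable-scorer perplexity, novelty against the training
data, all computed on 100 fixed-size resamples (10,000 words / 1,000
utterances) with Cohen's *d*, relative absolute differences and Student
*t*-tests between corpora; plus prosodic measures from TextGrid
alignments and pitch tracks (first-word accent F0, semitone F0 SD, vowels
per second, z-scored vowel durations) with Savitzky–Golay F0 smoothing.

**Synthetic CDS generator** — a stochastic grammar with age-dependent
mean utterance length, POS mix, Zipf lexicon and dependent-clause rate
that emits gold lemmas, UPOS tags and well-formed Universal Dependencies
trees, so the entire pipeline is testable without any external data.

## Worked example

Sample gold corpora at two ages from the developmental preset and compare
them with the measurement battery:

```r
library(cdsgen)
library(dplyr)

spec   <- cds_trend_preset("developmental", seed = 1)
gold6  <- sample_corpus(spec, age = 6,  n_utterances = 2000, seed = 6)
gold48 <- sample_corpus(spec, age = 48, n_utterances = 2000, seed = 48)

bind_rows("6"  = syntactic_profile(gold6),
          "48" = syntactic_profile(gold48), .id = "age")
#>   age   mean_utt_len dependent_clause_rate mean_tree_height
#> 1 6             4.02                0.0155             2.30
#> 2 48            5.98                0.0805             2.79
#>   mean_dependents_per_word avg_dependency_distance
#> 1                    0.751                    1.68
#> 2                    0.833                    2.25
```

Utterances lengthen from ~4 to ~6 words between 6 and 48 months, and all
tree-based complexity measures rise with them. Lexical richness is
compared at a fixed sample size (TTR is size-sensitive) via resampling:

```r
d6  <- subsampled_distribution(gold6,  lexical_profile, n_resamples = 50,
                               unit = "words", unit_size = 5000, seed = 2)
d48 <- subsampled_distribution(gold48, lexical_profile, n_resamples = 50,
                               unit = "words", unit_size = 5000, seed = 2)
effect_size(d48$ttr, d6$ttr)
#>   cohens_d relative_abs_difference_percent t_statistic   p_value mean_a mean_b
#> 1     61.0                            148.        305. 9.89e-148 0.0930 0.0375
```

The 48-month lexicon is far richer (TTR 0.093 vs 0.038 at 5,000 words; a
huge standardized effect because resample distributions are tight).
Prosodic measurement recovers constructed ground truth exactly:

```r
fx <- sample_prosody_fixture(contour = "peak", f0_base = 200, f0_peak = 310)
prosody_measures(fx$pitch, fx$alignment, smooth = FALSE)
#>   first_accent_f0_hz f0_sd_semitones tempo_vowels_per_sec mean_vowel_duration_s
#> 1                310            2.24                    5                  0.12
```

The full pipeline (synthesize → tokenize → train → generate → evaluate)
runs from a YAML config:

```r
cfg <- validate_config("my-config.yaml")   # empty file = full defaults
run_pipeline(cfg, "out/")
```

or from the shell via the thin wrapper
`Rscript inst/exec/cdsgen.R run --config my-config.yaml --out out/`.

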