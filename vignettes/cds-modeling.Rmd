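---
title: "Modeling age-conditioned child-directed speech: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling age-conditioned child-directed speech: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdsgen)
```

Child-directed speech (CDS) changes systematically with the child's age:
utterances lengthen, the caregiver lexicon grows, syntax becomes more
complex. `cdsgen` models this with a single age-conditioned neural
language model over normalized transcripts, generates new transcripts
from it at arbitrary conditioning ages, and quantifies how faithfully the
generated corpora track reference corpora. This vignette documents the
model, the measurement battery, the synthetic data generator the package
is validated on, and the numerical and design choices that were genuinely
open.

## Corpus representation and normalization

The unit of analysis is the *utterance*: a lower-cased, punctuation-free
word string delimited by a full stop. Normalization removes every
character outside `[a-z0-9' ]` — apostrophes are kept because
contractions ("doggy's") are lexical — and drops utterances containing
the CHAT-convention incomprehensible-speech markers `xxx`, `yyy`, `www`
(the list is an argument) or that become empty. Normalization is
idempotent by construction.

Utterances are assigned to 3-month age bins centered at 3, 6, ..., 84
months. The bin intervals are half-open, `[center - 1.5, center + 1.5)`,
so the assignment is a true partition; ages outside `[1.5, 85.5)` are
excluded and counted. Only mother/father utterances are retained when
reading transcript exports, and rows without age information are dropped
and counted, so full-scale runs can report the same bookkeeping a corpus
study would.

## Subword tokenization

A WordPiece vocabulary is trained on the *training bins only* (the
held-out validation bin is excluded, avoiding leakage — the alternative,
training the tokenizer on everything, would let validation tokens
influence segmentation). The initial vocabulary is the utterance-final
full stop plus every character in word-initial (`c`) and word-internal
(`##c`) position; adjacent pieces are then merged greedily by the
WordPiece score `count(ab) / (count(a) count(b))` until the requested
size (default 8,000) is reached, with ties broken lexicographically for
determinism. Pieces never span word boundaries, which gives two testable
contracts: exact encode/decode round-trips on any in-alphabet string, and
token counts at least as large as word counts. A vocabulary size the
corpus cannot support is an error that names the achievable size.

Training samples are consecutive non-overlapping `seq_len`-token windows
(default 100) of the concatenated per-bin token stream, the trailing
remainder discarded; each sample carries the age (bin center) of the bin
supplying its first token, so windows spanning a bin boundary take the
age of their first token. The default held-out bin is 57 months.

## The age-conditioned language model

The model is a decoder-only transformer in the GPT-2 style: token
embeddings plus *learned* positional embeddings combined by summation,
`n_blocks` pre-norm blocks of causally masked multi-head self-attention
and a GELU feed-forward layer, a final layer norm, and a softmax output
projection. Full-scale defaults: vocabulary 8,000, width 512, five
blocks, eight heads, dropout 0.05 on the residual branches, 100-token
inputs, Adam at learning rate 1e-4 with minibatches of 64, early stopping
on validation loss with patience 15, the best-validation-loss parameters
returned.

Age conditioning: the scalar age in months is divided by 84 (the last bin
center) and passed through a one-hidden-layer ReLU encoder to a
width-`embed_dim` vector, which is *concatenated in front of* the token
sequence. Three choices here were open and are fixed as follows:

* the age position receives **no positional embedding** — positional
  embeddings are described for word tokens only;
* the age position receives **no loss** — each *token* position predicts
  the next token; the age vector lengthens the attention sequence by one
  and is otherwise passive;
* the **age scaling** (÷ 84) simply conditions the optimizer; it is
  recorded in the configuration so checkpoints are self-describing.

Other recorded conventions: an epoch is one shuffled pass over all
training samples; the loss is the *mean* token cross-entropy in nats
(this affects only the reporting scale); dropout is not applied inside
the attention weights; input embeddings and the output projection are
not tied. Initialization, shuffling and dropout all derive from one
configured seed, so training is bit-reproducible.

The forward and backward passes are hand-written R matrix code.
Correctness is enforced two ways in the test suite: analytic gradients
are compared against central finite differences on a tiny model for a
sample of every parameter family, and closed forms are asserted (a model
with a zeroed output layer predicts uniformly and must show exactly
`ln(V)` nats of cross-entropy; an over-parameterized model must drive the
loss on a memorizable dataset below 0.1 nats). Checkpoints are
single-file JSON with the configuration and a hash of the training
vocabulary, so generation can refuse a mismatched vocabulary.

## Generation

Each sample starts from a seed prompt of 1–4 contiguous tokens drawn
uniformly from the training stream — by default from the stream of the
same age bin being generated, falling back to the full stream. Tokens
are then sampled one at a time from the model posterior, truncated to
the top-k (default 500) most probable tokens with ties at the k-th value
broken towards the lower token id (determinism requires *some* rule),
scaled by the temperature (default 1, i.e. the unmodified posterior),
and renormalized. Generation stops at 60 total tokens; the utterance
containing the seed and any trailing utterance not closed by a full stop
are discarded. The generated corpus records a per-sample sub-seed
derived from the master seed, so the whole corpus is reproducible and
individual samples can be replayed.

## The measurement battery

All corpus-level measures are computed on 100 random subsamples drawn
with replacement at fixed size — 10,000 words for lexical measures,
1,000 parsed utterances for syntactic measures — because several of them
(TTR above all) are sample-size dependent. Comparisons between two
corpora then operate on the two resample distributions: Cohen's *d*
(absolute mean difference over the pooled sample SD of the two
distributions), the relative absolute difference of the means in percent
with the *reference* corpus mean as denominator, and a two-tailed Student
*t*-test.

* **TTR** is computed over *lemmas*, not surface forms. Per-POS rates
  and per-POS lemma TTRs use the groups ADJ, ADV, NOUN, VERB, INTJ,
  PRON, DET and CONJ, where CONJ pools CCONJ and SCONJ.
* **Lexical divergence** draws a fixed-size word sample from each side,
  keeps lemmas occurring at least twice within their side, and computes
  Jensen–Shannon divergence over the union support. The logarithm base
  is 2, so the value lives in [0, 1] bits.
* **Syntactic complexity** comes from dependency trees: mean utterance
  length in words; the rate of utterances containing a dependent clause
  (any relation whose basename is in `advcl, ccomp, xcomp, acl, csubj`;
  configurable); tree height counted in *nodes* (a single word has
  height 1); mean direct dependents per word; and mean absolute
  position distance between a word and its head, with single-word
  utterances excluded from the distance mean (they have no non-root
  word) but included in every other measure by default.
* **Perplexity** is a pluggable-scorer measure: 100 strings of
  contiguous complete utterances totalling at least 50 words are drawn
  (start utterances sampled with replacement; strings may overlap), each
  scored as mean per-token negative log-likelihood by a user-supplied
  reference language model, and the mean of `exp(NLL)` is returned. The
  package deliberately does not bundle a reference LM.
* **Novelty** asks, for each generated utterance (final stop removed),
  whether its word string occurs as a contiguous subsequence of a
  *single* training utterance; matches do not cross training-utterance
  boundaries (a flag enables whole-stream search instead). Rates are
  reported by utterance length alongside the training corpus's own
  uniqueness curve (proportion of utterances occurring exactly once).
  The production implementation is a padded-string scan; the test suite
  proves it equivalent to a naive window-comparison oracle on hundreds
  of random corpora.
* **Age-trend reports** aggregate effect sizes per measure (averaged
  over bins) and per bin (averaged over measures), and fit second-order
  polynomials of each measure against age.

External morphosyntactic annotation is consumed, never produced: parsed
utterances enter as CoNLL-U (gold for synthetic data; any UD parser's
output for real data).

## Prosodic measures

Pitch tracks (time, F0, voicing — e.g. pYIN output) are preprocessed by
linear interpolation of F0 across unvoiced frames, nearest-value filling
at unvoiced edges, and Savitzky–Golay smoothing with third-order
polynomials in five-sample windows; timestamps and voicing flags are
never altered, and an order-3 filter is exact on cubic contours (an
acceptance check). Four measures follow, consumed from TextGrid
word/phone alignments:

* **pitch height**: the F0 of the first word's accent, operationalized
  as the maximum smoothed F0 in the first word's interval (the cited
  accent-detection literature gives no closed formula; the midpoint
  value is available as an alternative);
* **pitch variability**: the sample (n−1) standard deviation of
  `12·log2(f_i / mean f)` within the utterance — invariant under global
  rescaling of the contour;
* **tempo**: vowel phones per second over the aligned utterance span,
  with vowels identified by ARPABET label (stress digits ignored);
* **vowel duration**: z-scored per vowel label, pooled over the full
  comparison set, so intrinsic phone durations cancel while
  between-condition differences survive.

Condition-level reports add Shapiro–Wilk normality checks and rank-based
pairwise tests: the Wilcoxon signed-rank test when the two conditions
have equal sizes and pairing is requested, else the rank-sum analogue
(noted in the output). Identical paired samples are reported as p = 1
rather than the undefined statistic the raw test produces.

## The synthetic CDS generator

Because the full pipeline cannot be validated on real corpora in a
self-contained package, `cdsgen` ships a generator of gold-annotated
synthetic CDS. Each utterance is built by drawing a target length from
`1 + Poisson(mlu(age) − 1)`, drawing a POS bag from the age's POS rates,
and assembling a dependency tree from templated productions (verb root
with subject/object/adverbial slots, noun phrases with determiner and
adjective slots, coordination, an age-controlled probability of an
embedded `advcl`/`ccomp` clause that reserves two of the drawn slots so
utterance length stays on target). Lemmas are per-POS pseudo-words drawn
from a Zipf law whose support grows with `vocab_size(age)` (the noun
support can grow faster via `noun_ttr_slope`), which yields realistic
TTR and lexical-divergence behavior. Every tree is single-rooted,
acyclic and in-range by construction, and the test suite checks it.

Three presets ship: `flat` (no age dependence — the null condition),
`developmental` (MLU 4 → 6 words over 6 → 48 months, growing lexicon,
a U-shaped noun-rate bump peaking near 15–21 months, fading
interjections, rising clause rate — the qualitative shape reported for
real CDS), and `steep` (MLU 3 → 7 over 6 → 48 months; a deliberately
strong conditioning signal for recovery experiments).

What the generator does *not* emulate: semantic coherence, English
morphology (lemma = surface form), discourse structure, real caregiver
variation, disfluencies, or corpus heterogeneity. Passing tests
therefore demonstrate that the machinery measures and recovers what was
programmed into the data — not that a model trained on real CHILDES
would reach any particular fidelity.

Prosody fixtures are built analogously: consonant-vowel alignments with
configurable durations and an analytic F0 contour (constant, linear
rise, or a peak placed inside the first word), with the four measure
values recorded exactly as constructed. With smoothing disabled the
measured values must equal the constructed ones to 1e-6; contour
families are restricted to shapes that are linear across unvoiced gaps
so the interpolation path can also be validated exactly.

## The recovery study

`mlu_recovery_study()` is the package's end-to-end validation: a
synthetic corpus from the `steep` preset at ages 6, 18, 36, 48 (plus the
57-month validation bin), 8,000 utterances per bin (~200k tokens after
tokenization with a 200-piece vocabulary), a 2-block width-64 model with
32-token samples trained for up to 5 epochs at learning rate 1e-3, then
generation at the four conditioning ages under 5 independent sampling
seeds (25 samples of 30 tokens each, top-50). Recovery is declared when
the generated mean utterance length is monotone non-decreasing in age in
at least 4 of the 5 runs, and when the measurement battery applied to
5,000-utterance gold samples per bin recovers the programmed positive
age slope with Spearman ρ ≥ 0.9. These problem sizes keep the study
around six minutes on a single CPU while leaving the programmed age
signal far above the noise floor; at these sizes the trained model
separates the conditioning ages by roughly half a word of mean utterance
length per step, so the monotonicity check is not marginal.

## Pipeline and reproducibility

`validate_config()` normalizes a YAML configuration against the
full-scale defaults, rejecting unknown keys by name and listing all
range violations at once. `run_pipeline()` executes synthesize →
tokenize → train → generate → evaluate, writes every artifact (JSONL
corpora, CoNLL-U, vocabulary, checkpoint, per-epoch losses, metric
distributions, effect-size tables, novelty curves) under one output
directory, and lists each file with a content hash in a manifest; two
runs from the same configuration and seed produce identical manifests.
A single master seed deterministically derives per-stage, per-age and
per-sample sub-seeds. In the demonstration pipeline the generated side
has no dependency parses (the external parser is out of scope), so the
generated-vs-reference comparison covers the lexical battery plus mean
utterance length; on real data a UD parser's CoNLL-U output plugs into
the same report.

## Known limitations

* The transformer runs on CPU in plain R: full-scale training (8,000
  vocabulary, five 512-wide blocks, 51k-sample epochs) is possible but
  slow; the package's own experiments run at toy scale by design.
* Generation recomputes the full forward pass per token (no key-value
  cache), which is the dominant cost of large generation runs.
* The WordPiece trainer recomputes pair statistics per merge; fine for
  vocabularies in the thousands, not tuned for much larger ones.
* Perplexity requires a user-supplied scorer; none is bundled.
* The novelty scan is exact but O(corpus × corpus) in the worst case;
  the per-length report mitigates this in practice.
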