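test_that("sampled corpora hit the specified mean utterance length", {
  spec <- age_trend_spec(mlu = function(age) 4)
  gold <- sample_corpus(spec, age = 24, n_utterances = 5000, seed = 11)
  lens <- tabulate(gold$utt_id)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 4), 2 * se + 1e-12 + 0.05)
})

test_that("sampling is deterministic given a seed", {
  spec <- cds_trend_preset("developmental", seed = 5)
  a <- sample_corpus(spec, age = 12, n_utterances = 20)
  b <- sample_corpus(spec, age = 12, n_utterances = 20)
  expect_identical(a, b)
  c <- sample_corpus(spec, age = 12, n_utterances = 20, seed = 6)
  expect_false(identical(a, c))
})

test_that("a single-word-only spec forces trivial trees", {
  spec <- age_trend_spec(mlu = function(age) 1)
  gold <- sample_corpus(spec, age = 12, n_utterances = 200, seed = 3)
  expect_true(all(tabulate(gold$utt_id) == 1))
  expect_true(all(gold$head == 0))
  expect_true(all(gold$deprel == "root"))
})

test_that("emitted trees are UD well-formed across presets and ages", {
  for (preset in c("flat", "developmental", "steep")) {
    spec <- cds_trend_preset(preset, seed = 9)
    for (age in c(6, 21, 48)) {
      gold <- sample_corpus(spec, age, n_utterances = 150, seed = age)
      expect_true(check_trees(gold))
      counts <- gold |>
        dplyr::count(.data$utt_id, root = .data$head == 0) |>
        dplyr::filter(.data$root)
      expect_true(all(counts$n == 1))
    }
  }
})

test_that("pos_rates summing above one is rejected", {
  spec <- age_trend_spec(pos_rates = function(age) c(NOUN = 0.9, VERB = 0.8))
  expect_error(sample_corpus(spec, 12, 10), "sum")
})

test_that("realized POS rates approach the specified rates", {
  rates <- c(ADJ = 0.05, ADV = 0.07, NOUN = 0.3, VERB = 0.2, INTJ = 0.05,
             PRON = 0.15, DET = 0.1, CCONJ = 0.05, SCONJ = 0.03)
  spec <- age_trend_spec(mlu = function(age) 5,
                         pos_rates = function(age) rates,
                         dep_clause_rate = function(age) 0)
  gold <- sample_corpus(spec, 24, n_utterances = 4000, seed = 2)
  realized <- prop.table(table(gold$upos))[names(rates)]
  expect_true(all(abs(realized - rates) < 0.02))
})

test_that("CoNLL-U output round-trips gold annotation", {
  spec <- cds_trend_preset("developmental", seed = 1)
  gold <- sample_corpus(spec, age = 18, n_utterances = 100)
  text <- to_conllu(gold)
  back <- read_conllu(text)
  expect_equal(back$form, gold$form)
  expect_equal(back$lemma, gold$lemma)
  expect_equal(back$upos, gold$upos)
  expect_equal(back$head, gold$head)
  expect_equal(back$deprel, gold$deprel)
  expect_equal(back$utt_id, gold$utt_id)
  expect_equal(back$child_age_months, gold$child_age_months)
  # token-line arity: one line per token plus comments and separators
  n3 <- sum(gold$utt_id == 3)
  block <- strsplit(text, "\n\n", fixed = TRUE)[[1]][3]
  expect_equal(sum(!startsWith(strsplit(block, "\n")[[1]], "#")), n3)
  # file round-trip too
  path <- withr::local_tempfile(fileext = ".conllu")
  to_conllu(gold, path)
  expect_equal(read_conllu(path)$form, gold$form)
})

test_that("gold_to_corpus flattens forms in surface order", {
  spec <- cds_trend_preset("flat")
  gold <- sample_corpus(spec, 24, n_utterances = 30, seed = 4)
  corp <- gold_to_corpus(gold)
  expect_equal(nrow(corp), 30L)
  u1 <- gold[gold$utt_id == 1, ]
  expect_equal(corp$utterance[1],
               paste(u1$form[order(u1$position)], collapse = " "))
})
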