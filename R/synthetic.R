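#' Specify age trends for the synthetic CDS generator
#'
#' An `age_trend_spec` bundles the age-dependent knobs of the synthetic
#' child-directed-speech generator: mean utterance length (MLU, words),
#' lexicon size, part-of-speech composition, and the rate of utterances
#' carrying a dependent clause. Each knob is a function of child age in
#' months, so presets can encode developmental trajectories (CDS grows
#' from roughly four towards six words per utterance over the first four
#' years, with a richer vocabulary and more embedded clauses).
#'
#' @param mlu Function age -> mean utterance length in words (>= 1).
#' @param vocab_size Function age -> lexicon size (distinct lemmas
#'   available at that age).
#' @param pos_rates Function age -> named proportions over the UPOS
#'   classes ADJ, ADV, NOUN, VERB, INTJ, PRON, DET, CCONJ, SCONJ. Must be
#'   nonnegative and sum to <= 1; any remainder is assigned to NOUN.
#' @param dep_clause_rate Function age -> probability that an utterance of
#'   three or more words embeds a dependent clause (advcl/ccomp subtree).
#' @param noun_ttr_slope Relative growth per month of the noun lexicon on
#'   top of `vocab_size`, so noun type-token ratios can rise with age
#'   independently of the other classes.
#' @param zipf_exponent Exponent of the Zipf law lemmas are drawn from.
#' @param seed Default RNG seed used by [sample_corpus()].
#' @return An object of class `age_trend_spec`.
#' @export
age_trend_spec <- function(mlu = function(age) 4,
                           vocab_size = function(age) 200L,
                           pos_rates = function(age) c(
                             ADJ = 0.05, ADV = 0.07, NOUN = 0.22,
                             VERB = 0.20, INTJ = 0.05, PRON = 0.18,
                             DET = 0.12, CCONJ = 0.03, SCONJ = 0.02),
                           dep_clause_rate = function(age) 0.08,
                           noun_ttr_slope = 0,
                           zipf_exponent = 1,
                           seed = 1L) {
  stopifnot(is.function(mlu), is.function(vocab_size),
            is.function(pos_rates), is.function(dep_clause_rate))
  structure(list(mlu = mlu, vocab_size = vocab_size, pos_rates = pos_rates,
                 dep_clause_rate = dep_clause_rate,
                 noun_ttr_slope = noun_ttr_slope,
                 zipf_exponent = zipf_exponent, seed = as.integer(seed)),
            class = "age_trend_spec")
}

#' Built-in age-trend presets
#'
#' * `"flat"`: no age dependence (MLU 4, fixed lexicon and POS mix) — the
#'   null preset used to test that the analysis stack reports no trend.
#' * `"developmental"`: MLU rising from 4 to ~6 words between 6 and 48
#'   months, a growing lexicon, a U-shaped noun-rate bump peaking near
#'   15-21 months, declining interjections, and a rising dependent-clause
#'   rate — the qualitative shape of real CDS trajectories.
#' * `"steep"`: MLU rising from 3 to 7 words between 6 and 48 months with
#'   an age-dependent lexicon; a strong, easy-to-recover age signal used
#'   for LM conditioning experiments.
#'
#' @param name Preset name.
#' @param seed Default RNG seed stored in the spec.
#' @return An `age_trend_spec`.
#' @export
cds_trend_preset <- function(name = c("developmental", "flat", "steep"),
                             seed = 1L) {
  name <- match.arg(name)
  ramp <- function(age, from, to, a0 = 6, a1 = 48) {
    t <- pmin(pmax((age - a0) / (a1 - a0), 0), 1)
    from + (to - from) * t
  }
  base_rates <- c(ADJ = 0.05, ADV = 0.07, NOUN = 0.22, VERB = 0.20,
                  INTJ = 0.05, PRON = 0.18, DET = 0.12, CCONJ = 0.03,
                  SCONJ = 0.02)
  switch(name,
    flat = age_trend_spec(seed = seed),
    developmental = age_trend_spec(
      mlu = function(age) ramp(age, 4, 6),
      vocab_size = function(age) as.integer(150 + round(6 * age)),
      pos_rates = function(age) {
        r <- base_rates
        # noun-rate bump centered at 18 months; interjections fade with age
        r["NOUN"] <- r["NOUN"] + 0.06 * exp(-((age - 18) / 8)^2)
        r["INTJ"] <- 0.03 + 0.05 * exp(-age / 24)
        r["ADJ"] <- r["ADJ"] - 0.02 * exp(-((age - 18) / 8)^2)
        r["PRON"] <- r["PRON"] - 0.03 * exp(-((age - 18) / 8)^2)
        r / sum(r) * 0.99
      },
      dep_clause_rate = function(age) 0.04 + ramp(age, 0, 0.12),
      noun_ttr_slope = 0.02,
      seed = seed
    ),
    steep = age_trend_spec(
      mlu = function(age) ramp(age, 3, 7),
      vocab_size = function(age) as.integer(60 + round(2 * age)),
      pos_rates = function(age) base_rates,
      dep_clause_rate = function(age) 0.03 + ramp(age, 0, 0.1),
      seed = seed
    )
  )
}

upos_classes <- c("ADJ", "ADV", "NOUN", "VERB", "INTJ", "PRON", "DET",
                  "CCONJ", "SCONJ")

# draw n lemma indices from a truncated Zipf law on 1..support
rzipf <- function(n, support, s = 1) {
  p <- (1 / seq_len(support)^s)
  sample.int(support, n, replace = TRUE, prob = p / sum(p))
}

lexicon_word <- function(upos, index) {
  paste0(tolower(upos), index)
}

# per-UPOS lexicon support at a given age
pos_support <- function(spec, age) {
  v <- max(10L, as.integer(spec$vocab_size(age)))
  share <- c(ADJ = 0.10, ADV = 0.08, NOUN = 0.40, VERB = 0.25, INTJ = 0.04,
             PRON = 0.06, DET = 0.03, CCONJ = 0.02, SCONJ = 0.02)
  supp <- pmax(1L, as.integer(round(v * share)))
  names(supp) <- names(share)
  supp["NOUN"] <- max(1L, as.integer(round(
    supp["NOUN"] * (1 + spec$noun_ttr_slope * (age - 3)))))
  supp
}

# assemble a well-formed dependency tree over a bag of UPOS tags.
# Returns a tibble with position-ordered upos/deprel/head (1-based, 0 root).
build_tree <- function(bag, add_clause = FALSE) {
  if (add_clause) {
    # reserve two slots for the clause marker + embedded verb so the
    # utterance length stays on target
    bag <- c(bag[seq_len(length(bag) - 2L)], "VERB", "SCONJ")
  }
  n_id <- 0L
  nodes <- list()
  add_node <- function(upos, deprel, parent) {
    n_id <<- n_id + 1L
    nodes[[n_id]] <<- list(id = n_id, upos = upos, deprel = deprel,
                           parent = parent)
    n_id
  }
  counts <- table(factor(bag, levels = upos_classes))
  take <- function(upos, k = 1L) {
    k <- min(k, counts[[upos]])
    counts[[upos]] <<- counts[[upos]] - k
    k
  }

  order_ids <- integer(0)
  # root choice: prefer a verb, then a noun, then whatever is left
  root_pos <- if (counts[["VERB"]] > 0) "VERB"
    else if (counts[["NOUN"]] > 0) "NOUN"
    else upos_classes[which(counts > 0)[1]]
  take(root_pos)
  root <- add_node(root_pos, "root", 0L)

  noun_phrase <- function(deprel, parent) {
    ids <- integer(0)
    noun <- add_node("NOUN", deprel, parent)
    if (take("DET")) ids <- c(ids, add_node("DET", "det", noun))
    if (take("ADJ")) ids <- c(ids, add_node("ADJ", "amod", noun))
    c(ids, noun)
  }

  # interjections open the utterance
  while (take("INTJ")) order_ids <- c(order_ids, add_node("INTJ", "discourse", root))
  # subject: pronoun if available, else a noun phrase (verb roots only)
  if (take("PRON")) {
    order_ids <- c(order_ids, add_node("PRON", "nsubj", root))
  } else if (root_pos == "VERB" && counts[["NOUN"]] > 0) {
    take("NOUN")
    order_ids <- c(order_ids, noun_phrase("nsubj", root))
  }
  order_ids <- c(order_ids, root)
  # objects / nominal modifiers after the root
  obj_rel <- if (root_pos == "VERB") "obj" else "nmod"
  prev_obj <- 0L
  while (counts[["NOUN"]] > 0) {
    take("NOUN")
    if (prev_obj && take("CCONJ")) {
      cc <- add_node("CCONJ", "cc", NA)  # parent fixed to the conjunct below
      np <- noun_phrase("conj", prev_obj)
      nodes[[cc]]$parent <- np[length(np)]
      order_ids <- c(order_ids, cc, np)
    } else {
      np <- noun_phrase(if (prev_obj) "conj" else obj_rel,
                        if (prev_obj) prev_obj else root)
      order_ids <- c(order_ids, np)
    }
    prev_obj <- np[length(np)]
  }
  while (take("PRON")) order_ids <- c(order_ids, add_node("PRON", "obj", root))
  while (take("ADV")) order_ids <- c(order_ids, add_node("ADV", "advmod", root))
  while (take("ADJ")) order_ids <- c(order_ids, add_node("ADJ", "amod", root))
  while (take("DET")) order_ids <- c(order_ids, add_node("DET", "det", root))
  while (take("CCONJ")) order_ids <- c(order_ids, add_node("CCONJ", "cc", root))
  # dependent clause: marker + embedded verb at the end (only when asked
  # for, so the clause rate stays under the age trend's control); other
  # surplus verbs coordinate with the root
  clause_pending <- add_clause
  while (counts[["VERB"]] > 0) {
    take("VERB")
    if (clause_pending) {
      cl <- add_node("VERB", if (stats::runif(1) < 0.5) "advcl" else "ccomp",
                     root)
      if (take("SCONJ")) {
        order_ids <- c(order_ids, add_node("SCONJ", "mark", cl))
      }
      order_ids <- c(order_ids, cl)
      clause_pending <- FALSE
    } else {
      order_ids <- c(order_ids, add_node("VERB", "conj", root))
    }
  }
  while (take("SCONJ")) order_ids <- c(order_ids, add_node("SCONJ", "mark", root))

  pos_of <- match(seq_len(n_id), order_ids)
  tibble::tibble(
    position = seq_along(order_ids),
    upos = vapply(nodes[order_ids], `[[`, "", "upos"),
    deprel = vapply(nodes[order_ids], `[[`, "", "deprel"),
    head = vapply(order_ids, function(id) {
      p <- nodes[[id]]$parent
      if (p == 0L) 0L else pos_of[p]
    }, 0L)
  )
}

#' Sample a synthetic gold-annotated CDS corpus at one age
#'
#' Draws `n_utterances` utterances from a stochastic grammar whose mean
#' utterance length, POS composition, lexicon size, and dependent-clause
#' rate follow `spec` at the given age. Every utterance carries gold
#' lemmas, UPOS tags, and a well-formed single-rooted dependency tree.
#' Lemmas are pseudo-words (`noun12`, `verb3`, ...) drawn from a Zipf law
#' whose support grows with `spec$vocab_size(age)`, so type-token ratios
#' and lexical divergence behave realistically.
#'
#' @param spec An [age_trend_spec()].
#' @param age Child age in months.
#' @param n_utterances Number of utterances to draw.
#' @param seed RNG seed (defaults to the seed stored in `spec`).
#' @return A tibble with one row per token: `utt_id`, `child_age_months`,
#'   `position`, `form`, `lemma`, `upos`, `head` (1-based, 0 = root),
#'   `deprel`.
#' @export
sample_corpus <- function(spec, age, n_utterances, seed = spec$seed) {
  stopifnot(inherits(spec, "age_trend_spec"), n_utterances >= 1)
  rates <- spec$pos_rates(age)
  rates <- rates[upos_classes]
  rates[is.na(rates)] <- 0
  names(rates) <- upos_classes
  if (any(rates < 0)) stop("pos_rates must be nonnegative", call. = FALSE)
  if (sum(rates) > 1 + 1e-8) stop("pos_rates sum to more than 1", call. = FALSE)
  rates["NOUN"] <- rates["NOUN"] + (1 - sum(rates))
  mlu <- spec$mlu(age)
  if (mlu < 1) stop("mlu(age) must be >= 1", call. = FALSE)
  p_dep <- spec$dep_clause_rate(age)
  supp <- pos_support(spec, age)

  out <- withr::with_seed(seed, {
    lens <- 1L + stats::rpois(n_utterances, mlu - 1)
    trees <- lapply(seq_len(n_utterances), function(i) {
      bag <- sample(upos_classes, lens[i], replace = TRUE, prob = rates)
      add_clause <- lens[i] >= 3 && stats::runif(1) < p_dep
      tr <- build_tree(bag, add_clause)
      tr$utt_id <- i
      tr
    })
    tab <- dplyr::bind_rows(trees)
    idx <- integer(nrow(tab))
    for (u in upos_classes) {
      rows <- which(tab$upos == u)
      if (length(rows)) {
        idx[rows] <- rzipf(length(rows), supp[[u]], spec$zipf_exponent)
      }
    }
    tab$lemma <- lexicon_word(tab$upos, idx)
    tab
  })
  out$form <- out$lemma
  out$child_age_months <- as.numeric(age)
  out[, c("utt_id", "child_age_months", "position", "form", "lemma",
          "upos", "head", "deprel")]
}

#' Flatten a gold token table to a plain utterance corpus
#'
#' @param gold A gold token tibble from [sample_corpus()].
#' @param corpus_id Corpus identifier stored on every row.
#' @return A corpus tibble (see [normalize_corpus()]).
#' @export
gold_to_corpus <- function(gold, corpus_id = "synthetic") {
  gold |>
    dplyr::group_by(.data$utt_id) |>
    dplyr::summarise(
      utterance = paste(.data$form[order(.data$position)], collapse = " "),
      child_age_months = .data$child_age_months[1],
      .groups = "drop"
    ) |>
    dplyr::transmute(
      utterance = .data$utterance,
      speaker_role = "mother",
      child_age_months = .data$child_age_months,
      corpus_id = corpus_id
    )
}
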