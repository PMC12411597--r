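#' Relations treated as introducing a dependent clause
#' @keywords internal
clausal_deprels <- c("advcl", "ccomp", "xcomp", "acl", "csubj")

# vectorized per-utterance tree statistics; heads are chased globally so
# one pass per tree level covers the whole corpus
tree_stats <- function(parsed, clause_rels) {
  parsed <- parsed[order(parsed$utt_id, parsed$position), , drop = FALSE]
  utt <- match(parsed$utt_id, unique(parsed$utt_id))
  n_tok <- nrow(parsed)
  len <- tabulate(utt)
  first_row <- cumsum(c(1L, len[-length(len)]))
  roots_per_utt <- tabulate(utt[parsed$head == 0], nbins = length(len))
  if (any(roots_per_utt != 1)) {
    bad <- unique(parsed$utt_id)[which(roots_per_utt != 1)[1]]
    stop("malformed tree in utterance ", bad, ": expected exactly one root",
         call. = FALSE)
  }
  if (any(parsed$head < 0 | parsed$head > len[utt])) {
    bad <- parsed$utt_id[which(parsed$head > len[utt] | parsed$head < 0)[1]]
    stop("malformed tree in utterance ", bad, ": head out of range",
         call. = FALSE)
  }
  glob_head <- ifelse(parsed$head == 0, 0L,
                      first_row[utt] + parsed$head - 1L)
  depth <- rep(1L, n_tok)
  ptr <- glob_head
  pass <- 0L
  while (any(ptr > 0)) {
    pass <- pass + 1L
    if (pass > max(len)) {
      bad <- parsed$utt_id[which(ptr > 0)[1]]
      stop("malformed tree in utterance ", bad, ": cyclic head graph",
           call. = FALSE)
    }
    live <- ptr > 0
    depth[live] <- depth[live] + 1L
    ptr[live] <- glob_head[ptr[live]]
  }
  non_root <- parsed$head != 0
  base_rel <- sub(":.*$", "", parsed$deprel)
  list(
    len = len,
    height = as.integer(tapply(depth, utt, max)),
    sum_distance = sum(abs(parsed$position[non_root] -
                             parsed$head[non_root])),
    n_distance = sum(non_root),
    has_clause = as.logical(
      tapply(base_rel %in% clause_rels, utt, any))
  )
}

#' Syntactic complexity profile of parsed utterances
#'
#' Computes the five tree-based complexity measures over a set of parsed
#' utterances: mean utterance length in words, rate of utterances
#' containing a dependent clause, mean syntactic tree height (counted in
#' nodes, so a single word has height 1), mean number of direct dependents
#' per word, and average dependency distance (mean over non-root words of
#' the absolute position difference to the head; single-word utterances do
#' not contribute to the distance mean).
#'
#' @param parsed A gold/parsed token table (`utt_id`, `position`, `head`,
#'   `deprel`; see [sample_corpus()], [read_conllu()]).
#' @param clause_rels Dependency relations (basenames) counted as
#'   dependent clauses.
#' @return A one-row tibble with `mean_utt_len`, `dependent_clause_rate`,
#'   `mean_tree_height`, `mean_dependents_per_word`,
#'   `avg_dependency_distance`.
#' @export
syntactic_profile <- function(parsed, clause_rels = clausal_deprels) {
  stopifnot(is.data.frame(parsed), nrow(parsed) > 0)
  st <- tree_stats(parsed, clause_rels)
  tibble::tibble(
    mean_utt_len = mean(st$len),
    dependent_clause_rate = mean(st$has_clause),
    mean_tree_height = mean(st$height),
    # every non-root word is some word's direct dependent
    mean_dependents_per_word = sum(st$len - 1L) / sum(st$len),
    avg_dependency_distance =
      if (st$n_distance > 0) st$sum_distance / st$n_distance else NA_real_
  )
}

#' Mean utterance perplexity under a pluggable scorer
#'
#' Samples `n_strings` strings of contiguous complete utterances, each
#' totalling at least `min_words` words, scores each string with the
#' supplied reference language-model scorer (a function mapping a text
#' string to its mean per-token negative log-likelihood in nats), and
#' returns the mean of `exp(NLL)` over the strings.
#'
#' Strings are built by drawing a start utterance uniformly with
#' replacement and appending following utterances until the word budget is
#' met; each utterance is terminated by a full stop in the scored string.
#'
#' @param corpus A corpus tibble (see [normalize_corpus()]).
#' @param scorer Function `character -> numeric` (mean per-token NLL,
#'   nats).
#' @param n_strings Number of strings to score.
#' @param min_words Minimum words per string.
#' @param seed RNG seed.
#' @return Mean perplexity (scalar).
#' @export
perplexity_profile <- function(corpus, scorer, n_strings = 100L,
                               min_words = 50L, seed = 1L) {
  stopifnot(is.data.frame(corpus), is.function(scorer))
  words_per_utt <- lengths(strsplit(corpus$utterance, " ", fixed = TRUE))
  if (sum(words_per_utt) < min_words) {
    stop("corpus has fewer than `min_words` words; cannot build a string",
         call. = FALSE)
  }
  n_utt <- nrow(corpus)
  withr::with_seed(seed, {
    nll <- vapply(seq_len(n_strings), function(i) {
      start <- sample.int(n_utt, 1L)
      idx <- start
      total <- words_per_utt[start]
      j <- start
      while (total < min_words) {
        j <- if (j == n_utt) 1L else j + 1L
        idx <- c(idx, j)
        total <- total + words_per_utt[j]
      }
      scorer(paste0(paste(corpus$utterance[idx], collapse = " . "), " ."))
    }, 0.0)
    mean(exp(nll))
  })
}
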