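pos_groups <- c("ADJ", "ADV", "NOUN", "VERB", "INTJ", "PRON", "DET", "CONJ")

# CONJ is the joint class of coordinating and subordinating conjunctions
pos_group_of <- function(upos) {
  ifelse(upos %in% c("CCONJ", "SCONJ"), "CONJ", upos)
}

#' Lexical richness profile of an annotated word sample
#'
#' Computes the type-token ratio (TTR) of lemmas, the rate of each
#' part-of-speech group among all words, and the within-group lemma TTR,
#' for the groups ADJ, ADV, NOUN, VERB, INTJ, PRON, DET and CONJ (CONJ
#' pooling CCONJ and SCONJ).
#'
#' @param tokens A data frame with columns `lemma` and `upos` (one row per
#'   word token), e.g. from [sample_corpus()] or [read_conllu()].
#' @return A one-row tibble: `ttr`, `rate_<group>` and `ttr_<group>` for
#'   each POS group (`ttr_<group>` is `NA` when the group is absent).
#' @examples
#' lexical_profile(tibble::tibble(
#'   lemma = c("a", "b", "a", "c"), upos = "NOUN"))
#' @export
lexical_profile <- function(tokens) {
  stopifnot(is.data.frame(tokens), nrow(tokens) > 0,
            all(c("lemma", "upos") %in% names(tokens)))
  n <- nrow(tokens)
  grp <- pos_group_of(tokens$upos)
  out <- list(ttr = length(unique(tokens$lemma)) / n)
  for (g in pos_groups) {
    in_g <- grp == g
    out[[paste0("rate_", g)]] <- sum(in_g) / n
    out[[paste0("ttr_", g)]] <- if (any(in_g)) {
      length(unique(tokens$lemma[in_g])) / sum(in_g)
    } else {
      NA_real_
    }
  }
  tibble::as_tibble(out)
}

#' Jensen-Shannon divergence between two probability vectors
#'
#' Base-2 JSD, so the value lies in `[0, 1]`; 0 iff the distributions are
#' equal and 1 for disjoint supports.
#'
#' @param p,q Nonnegative vectors of equal length (normalized internally).
#' @return The divergence in bits.
#' @export
js_divergence <- function(p, q) {
  stopifnot(length(p) == length(q), all(p >= 0), all(q >= 0),
            sum(p) > 0, sum(q) > 0)
  p <- p / sum(p)
  q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Lexical divergence between a sample and a reference corpus
#'
#' Draws a fixed-size word sample from each side, keeps lemmas occurring
#' at least twice within the side, builds frequency distributions over the
#' union support, and returns their base-2 Jensen-Shannon divergence.
#' Lower values mean more similar lemma frequency profiles.
#'
#' @param sample_a,reference_b Data frames with a `lemma` column (one row
#'   per word token).
#' @param sample_size Words drawn from each side.
#' @param min_count Minimum within-side lemma count to enter the
#'   distribution.
#' @param seed RNG seed for the subsampling.
#' @return The divergence in bits.
#' @export
lexical_divergence <- function(sample_a, reference_b, sample_size = 10000L,
                               min_count = 2L, seed = 1L) {
  stopifnot("lemma" %in% names(sample_a), "lemma" %in% names(reference_b))
  if (nrow(sample_a) < sample_size || nrow(reference_b) < sample_size) {
    stop("both sides need at least `sample_size` (", sample_size, ") words",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    a <- sample(sample_a$lemma, sample_size)
    b <- sample(reference_b$lemma, sample_size)
    ca <- table(a)
    cb <- table(b)
    ca <- ca[ca >= min_count]
    cb <- cb[cb >= min_count]
    if (length(ca) == 0 || length(cb) == 0) {
      stop("no lemma reaches the minimum count; cannot form distributions",
           call. = FALSE)
    }
    support <- union(names(ca), names(cb))
    p <- as.numeric(ca[support])
    q <- as.numeric(cb[support])
    p[is.na(p)] <- 0
    q[is.na(q)] <- 0
    js_divergence(p, q)
  })
}
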