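#' Train a WordPiece subword vocabulary
#'
#' Learns a subword vocabulary of exactly `size` pieces from a normalized
#' corpus, in the BERT WordPiece style: the initial vocabulary is the
#' utterance-final full stop plus every character observed word-initially
#' (`c`) and word-internally (`##c`); pairs of adjacent pieces inside words
#' are then merged greedily by the WordPiece score
#' `count(ab) / (count(a) * count(b))` until `size` pieces exist. Pieces
#' never span word boundaries, so any in-alphabet string round-trips
#' exactly through [wp_encode()] / [wp_decode()].
#'
#' @param corpus A corpus tibble (see [normalize_corpus()]) or a character
#'   vector of space-separated normalized utterances.
#' @param size Total vocabulary size (the default mirrors the usual
#'   working size of 8000; tests use much smaller values).
#' @return An object of class `wordpiece_vocab`: pieces (character vector;
#'   id = position - 1, so ids run 0..size-1), `size`, and
#'   `end_of_utterance_id`, the id of the full-stop piece.
#' @export
train_subword_vocab <- function(corpus, size = 8000L) {
  utts <- if (is.data.frame(corpus)) corpus$utterance else as.character(corpus)
  stopifnot(length(utts) > 0, size >= 2)
  words <- unlist(strsplit(utts, " ", fixed = TRUE), use.names = FALSE)
  words <- words[nzchar(words)]
  if (length(words) == 0) stop("corpus contains no words", call. = FALSE)
  wtab <- table(words)
  wfreq <- as.numeric(wtab)
  wstr <- names(wtab)

  # seed segmentation: first char bare, rest as ##c continuations
  segs <- lapply(strsplit(wstr, "", fixed = TRUE), function(ch) {
    if (length(ch) > 1) ch[-1] <- paste0("##", ch[-1])
    ch
  })
  alphabet <- sort(unique(unlist(segs, use.names = FALSE)))
  pieces <- c(".", alphabet)
  if (length(pieces) > size) {
    stop("size ", size, " is below the alphabet size; need at least ",
         length(pieces), call. = FALSE)
  }

  while (length(pieces) < size) {
    # pair statistics over adjacent pieces within words, weighted by word freq
    multi <- which(lengths(segs) > 1)
    if (length(multi) == 0) {
      stop("corpus supports at most ", length(pieces),
           " pieces; requested ", size, call. = FALSE)
    }
    lens <- lengths(segs[multi])
    left <- unlist(lapply(segs[multi], function(s) s[-length(s)]),
                   use.names = FALSE)
    right <- unlist(lapply(segs[multi], function(s) s[-1]), use.names = FALSE)
    w <- rep(wfreq[multi], lens - 1)
    pair_key <- paste(left, right, sep = "\t")
    pair_cnt <- rowsum(w, pair_key)
    # unigram piece counts over all words
    unit_cnt <- rowsum(rep(wfreq, lengths(segs)),
                       unlist(segs, use.names = FALSE))
    keys <- rownames(pair_cnt)
    parts <- strsplit(keys, "\t", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    score <- pair_cnt[, 1] / (unit_cnt[a, 1] * unit_cnt[b, 1])
    best <- order(-score, keys)[1]  # ties broken lexicographically
    ba <- a[best]; bb <- b[best]
    merged <- paste0(ba, sub("^##", "", bb))
    pieces <- c(pieces, merged)
    # apply the merge to every segmentation containing the pair
    hit <- vapply(segs, function(s) {
      n <- length(s)
      n > 1 && any(s[-n] == ba & s[-1] == bb)
    }, NA)
    segs[hit] <- lapply(segs[hit], function(s) {
      i <- 1L
      out <- character(0)
      while (i <= length(s)) {
        if (i < length(s) && s[i] == ba && s[i + 1L] == bb) {
          out <- c(out, merged)
          i <- i + 2L
        } else {
          out <- c(out, s[i])
          i <- i + 1L
        }
      }
      out
    })
  }
  new_wordpiece_vocab(pieces)
}

new_wordpiece_vocab <- function(pieces) {
  lookup <- new.env(parent = emptyenv(), size = length(pieces) * 2L)
  for (i in seq_along(pieces)) assign(pieces[i], i - 1L, envir = lookup)
  structure(
    list(pieces = pieces, size = length(pieces),
         end_of_utterance_id = get(".", envir = lookup), lookup = lookup),
    class = "wordpiece_vocab"
  )
}

#' @export
print.wordpiece_vocab <- function(x, ...) {
  cat("<wordpiece_vocab> ", x$size, " pieces; end-of-utterance id ",
      x$end_of_utterance_id, "\n", sep = "")
  invisible(x)
}

#' Serialize / load a WordPiece vocabulary
#'
#' The vocabulary is stored as a JSON object mapping piece string to
#' 0-based integer id.
#'
#' @param vocab A `wordpiece_vocab`.
#' @param path File path.
#' @export
write_vocab <- function(vocab, path) {
  ids <- as.list(stats::setNames(seq_along(vocab$pieces) - 1L, vocab$pieces))
  jsonlite::write_json(ids, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  ids <- jsonlite::fromJSON(path)
  pieces <- names(sort(unlist(ids)))
  new_wordpiece_vocab(pieces)
}

wp_encode_word <- function(word, lookup) {
  n <- nchar(word)
  ids <- integer(0)
  pos <- 1L
  first <- TRUE
  while (pos <= n) {
    end <- n
    found <- -1L
    while (end >= pos) {
      piece <- substr(word, pos, end)
      if (!first) piece <- paste0("##", piece)
      hit <- get0(piece, envir = lookup, inherits = FALSE)
      if (!is.null(hit)) {
        found <- hit
        break
      }
      end <- end - 1L
    }
    if (found < 0L) {
      stop("cannot encode word `", word,
           "`: character outside the vocabulary alphabet", call. = FALSE)
    }
    ids <- c(ids, found)
    pos <- end + 1L
    first <- FALSE
  }
  ids
}

#' Encode / decode utterances with a WordPiece vocabulary
#'
#' `wp_encode()` maps each utterance (space-separated normalized words) to a
#' vector of 0-based token ids using greedy longest-match segmentation, and
#' appends the full-stop id as the utterance terminator. `wp_decode()`
#' inverts it, returning space-separated word strings (one per full-stop
#' delimited utterance, terminator not included in the words).
#'
#' @param vocab A `wordpiece_vocab`.
#' @param utterances Character vector of normalized utterances.
#' @param append_stop Append the end-of-utterance full-stop id.
#' @return `wp_encode()`: a list of integer vectors. `wp_decode()`: a
#'   character vector of utterances.
#' @export
wp_encode <- function(vocab, utterances, append_stop = TRUE) {
  stopifnot(inherits(vocab, "wordpiece_vocab"))
  cache <- new.env(parent = emptyenv())
  stop_id <- vocab$end_of_utterance_id
  lapply(strsplit(utterances, " ", fixed = TRUE), function(ws) {
    ws <- ws[nzchar(ws)]
    ids <- unlist(lapply(ws, function(w) {
      hit <- get0(w, envir = cache, inherits = FALSE)
      if (is.null(hit)) {
        hit <- wp_encode_word(w, vocab$lookup)
        assign(w, hit, envir = cache)
      }
      hit
    }), use.names = FALSE)
    if (append_stop) ids <- c(ids, stop_id)
    as.integer(ids)
  })
}

#' @rdname wp_encode
#' @param ids Integer vector of 0-based token ids (one stream, possibly
#'   containing several full-stop delimited utterances).
#' @param drop_incomplete Drop a trailing utterance not closed by a full
#'   stop.
#' @export
wp_decode <- function(vocab, ids, drop_incomplete = FALSE) {
  stopifnot(inherits(vocab, "wordpiece_vocab"))
  ids <- as.integer(ids)
  if (any(ids < 0 | ids >= vocab$size)) {
    stop("token id outside the vocabulary", call. = FALSE)
  }
  pieces <- vocab$pieces[ids + 1L]
  utts <- character(0)
  cur_words <- character(0)
  cur <- ""
  flush_word <- function() if (nzchar(cur)) c(cur_words, cur) else cur_words
  for (p in pieces) {
    if (p == ".") {
      cur_words <- flush_word()
      utts <- c(utts, paste(cur_words, collapse = " "))
      cur_words <- character(0)
      cur <- ""
    } else if (startsWith(p, "##")) {
      cur <- paste0(cur, substr(p, 3L, nchar(p)))
    } else {
      cur_words <- flush_word()
      cur <- p
    }
  }
  if (!drop_incomplete && (nzchar(cur) || length(cur_words))) {
    utts <- c(utts, paste(flush_word(), collapse = " "))
  }
  utts
}

#' Build fixed-length LM training samples from an age-binned corpus
#'
#' Encodes each age bin, concatenates the non-holdout bins (ascending bin
#' order) into one token stream, and cuts it into consecutive
#' non-overlapping windows of `seq_len` tokens; the trailing remainder is
#' discarded. Each sample is labelled with the age (bin center, months) of
#' the bin supplying its first token. The validation set is built the same
#' way from the holdout bin alone.
#'
#' @param corpus An age-binned corpus tibble (see [bin_by_age()]).
#' @param vocab A `wordpiece_vocab`.
#' @param seq_len Tokens per sample.
#' @param holdout_bin Bin center (months) reserved for validation.
#' @return A list with elements `train` and `valid`, each a
#'   `training_dataset`: integer matrix `ids` (samples x seq_len, 0-based)
#'   plus per-sample `age` in months.
#' @export
make_training_samples <- function(corpus, vocab, seq_len = 100L,
                                  holdout_bin = 57L) {
  stopifnot(is.data.frame(corpus), "age_bin" %in% names(corpus))
  bins <- sort(unique(corpus$age_bin))
  if (!holdout_bin %in% bins) {
    stop("holdout bin ", holdout_bin, " is empty", call. = FALSE)
  }
  stream_of <- function(centers) {
    ids <- integer(0)
    ages <- numeric(0)
    for (b in centers) {
      utts <- corpus$utterance[corpus$age_bin == b]
      enc <- unlist(wp_encode(vocab, utts), use.names = FALSE)
      ids <- c(ids, enc)
      ages <- c(ages, rep(as.numeric(b), length(enc)))
    }
    list(ids = ids, ages = ages)
  }
  cut_samples <- function(stream) {
    n <- floor(length(stream$ids) / seq_len)
    if (n == 0) {
      warning("token stream shorter than seq_len; 0 samples produced",
              call. = FALSE)
      return(new_training_dataset(
        matrix(integer(0), 0, seq_len), numeric(0), vocab$size))
    }
    used <- n * seq_len
    ids <- matrix(stream$ids[seq_len(used)], nrow = n, ncol = seq_len,
                  byrow = TRUE)
    age <- stream$ages[(seq_len(n) - 1L) * seq_len + 1L]
    new_training_dataset(ids, age, vocab$size)
  }
  list(
    train = cut_samples(stream_of(setdiff(bins, holdout_bin))),
    valid = cut_samples(stream_of(holdout_bin))
  )
}

new_training_dataset <- function(ids, age, vocab_size) {
  structure(list(ids = ids, age = age, seq_len = ncol(ids),
                 vocab_size = vocab_size, n = nrow(ids)),
            class = "training_dataset")
}

#' @export
print.training_dataset <- function(x, ...) {
  cat("<training_dataset> ", x$n, " samples of ", x$seq_len,
      " tokens (vocab ", x$vocab_size, ")\n", sep = "")
  invisible(x)
}
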