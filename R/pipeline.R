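pipeline_defaults <- function() {
  list(
    rng_seed = 1L,
    synthetic = list(
      preset = "developmental",
      ages = c(6, 9, 12, 15, 18, 21, 24, 36, 48, 57, 60),
      n_utterances = 2000L
    ),
    corpus = list(
      vocab_size = 8000L,
      seq_len = 100L,
      holdout_bin = 57L,
      drop_markers = c("xxx", "yyy", "www")
    ),
    lm = list(
      embed_dim = 512L, n_blocks = 5L, n_heads = 8L, dropout = 0.05,
      age_hidden_dim = 512L, mlp_ratio = 4L, lr = 1e-4,
      batch_size = 64L, patience = 15L, max_epochs = 500L,
      age_scale = 84
    ),
    generation = list(
      temperature = 1, top_k = 500L, sample_len_tokens = 60L,
      seed_len_range = c(1L, 4L), n_samples_per_age = 2000L,
      ages = c(6, 9, 12, 15, 18, 21, 24, 36, 48)
    ),
    text_eval = list(
      n_resamples = 100L, lexical_unit = 10000L, syntactic_unit = 1000L,
      perplexity_n_strings = 100L, perplexity_min_words = 50L,
      divergence_reference_age = 60, divergence_sample_size = 10000L
    )
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) return(user)
  extra <- setdiff(names(user), names(defaults))
  if (length(extra)) {
    stop("unknown configuration key", if (length(extra) > 1) "s", ": ",
         paste(c(path, extra[1]), collapse = "."),
         call. = FALSE)
  }
  out <- defaults
  for (k in names(user)) {
    out[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      user[[k]]
    }
  }
  out
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), fills every missing
#' field with the full-scale default (vocabulary 8,000; five
#' 512-dimensional blocks, eight heads, dropout 0.05; 100-token inputs;
#' Adam lr 1e-4, batch 64, patience 15; top-500 temperature-1 sampling of
#' 60-token samples, 2,000 per age; 100 resamples of 10,000 words /
#' 1,000 utterances; 100 perplexity strings of >= 50 words), rejects
#' unknown keys by name, and range-checks every block (all violations
#' listed together).
#'
#' @param config Path to a YAML file, or a (possibly empty) list.
#' @return A normalized list of class `pipeline_config`.
#' @export
validate_config <- function(config = list()) {
  user <- if (is.character(config)) {
    yaml::read_yaml(config) %||% list()
  } else {
    config %||% list()
  }
  cfg <- merge_config(pipeline_defaults(), user)
  problems <- character(0)
  note <- function(ok, msg) {
    if (!isTRUE(ok)) problems <<- c(problems, msg)
  }
  lmcfg <- tryCatch(
    do.call(age_lm_config, c(list(vocab_size = cfg$corpus$vocab_size,
                                  seq_len = cfg$corpus$seq_len,
                                  rng_seed = cfg$rng_seed), cfg$lm)),
    error = function(e) conditionMessage(e))
  if (is.character(lmcfg)) problems <- c(problems, lmcfg)
  gencfg <- tryCatch(
    do.call(generation_config,
            c(cfg$generation[setdiff(names(cfg$generation), "ages")],
              list(rng_seed = cfg$rng_seed))),
    error = function(e) conditionMessage(e))
  if (is.character(gencfg)) problems <- c(problems, "generation: invalid")
  note(cfg$synthetic$n_utterances >= 1, "synthetic.n_utterances must be >= 1")
  note(all(cfg$text_eval$n_resamples >= 1), "text_eval.n_resamples must be >= 1")
  note(cfg$corpus$holdout_bin %% 3 == 0,
       "corpus.holdout_bin must be a 3-month bin center")
  note(all(cfg$generation$ages >= 0), "generation.ages must be nonnegative")
  if (length(problems)) {
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  cfg$lm_config <- lmcfg
  cfg$generation_config <- gencfg
  structure(cfg, class = "pipeline_config")
}

# gold annotation for the synthetic pseudo-word language: the UPOS class
# is recoverable from the lemma prefix, and lemma = surface form
annotate_pseudo_corpus <- function(corpus) {
  words <- strsplit(corpus$utterance, " ", fixed = TRUE)
  n <- lengths(words)
  w <- unlist(words, use.names = FALSE)
  upos <- toupper(sub("[0-9]+$", "", w))
  tibble::tibble(
    utt_id = rep(seq_along(n), n),
    child_age_months = rep(corpus$child_age_months, n),
    form = w, lemma = w, upos = upos
  )
}

#' Run the demonstration pipeline end-to-end
#'
#' Executes the full text path on the synthetic CDS language: sample an
#' age-stratified gold reference corpus, bin it, train a WordPiece
#' vocabulary on the training bins, build fixed-length samples, train
#' the age-conditioned LM with early stopping, generate an
#' age-conditioned corpus by top-k sampling, and evaluate it against the
#' reference (lexical profiles, mean utterance length, lexical
#' divergence, novelty, effect sizes). Every artifact is written under
#' `out_dir` and listed with a content hash in `manifest.json`; all
#' randomness derives from `config$rng_seed`.
#'
#' @param config A `pipeline_config` (see [validate_config()]).
#' @param out_dir Output directory (created).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main artifacts (`fit`, `report`,
#'   `novelty`, paths).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "report"), showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  artifacts <- character(0)
  put <- function(rel, writer) {
    path <- file.path(out_dir, rel)
    writer(path)
    artifacts <<- c(artifacts, rel)
    path
  }
  put(file.path("config.yaml"), function(p) {
    yaml::write_yaml(unclass(config)[setdiff(names(config),
      c("lm_config", "generation_config"))], p)
  })

  # --- stage 1: synthetic reference corpus with gold annotation
  say("synthesizing reference corpus (preset ", config$synthetic$preset,
      ", ", config$synthetic$n_utterances, " utterances/bin)")
  spec <- cds_trend_preset(config$synthetic$preset,
                           seed = config$rng_seed)
  gold_by_age <- lapply(config$synthetic$ages, function(a) {
    sample_corpus(spec, a, config$synthetic$n_utterances,
                  seed = (config$rng_seed * 131L + round(a)) %% 2147483111L)
  })
  names(gold_by_age) <- as.character(config$synthetic$ages)
  reference <- dplyr::bind_rows(lapply(gold_by_age, gold_to_corpus))
  reference <- bin_by_age(reference)
  say(nrow(reference), " reference utterances in ",
      length(unique(reference$age_bin)), " bins")
  put("reference.jsonl", function(p) write_corpus(reference, p))
  for (a in names(gold_by_age)) {
    put(file.path(paste0("reference_", a, ".conllu")),
        function(p) to_conllu(gold_by_age[[a]], p))
  }

  # --- stage 2: vocabulary (training bins only) and samples
  train_corpus <- reference[reference$age_bin != config$corpus$holdout_bin, ]
  vocab <- train_subword_vocab(train_corpus, config$corpus$vocab_size)
  say("vocabulary: ", vocab$size, " pieces")
  put("vocab.json", function(p) write_vocab(vocab, p))
  ds <- make_training_samples(reference, vocab,
                              seq_len = config$corpus$seq_len,
                              holdout_bin = config$corpus$holdout_bin)
  say(ds$train$n, " training samples, ", ds$valid$n,
      " validation samples of ", config$corpus$seq_len, " tokens")

  # --- stage 3: train the LM
  model <- build_age_lm(config$lm_config)
  fit <- train_age_lm(model, ds$train, ds$valid, quiet = quiet)
  say("best epoch ", fit$best_epoch, " (valid loss ",
      round(fit$best_valid_loss, 4), ")")
  put("model.json", function(p) write_age_lm(fit$model, p, vocab))
  put("history.csv", function(p) readr::write_csv(fit$history, p,
                                                  progress = FALSE))

  # --- stage 4: generate
  gen_ages <- intersect(config$generation$ages,
                        unique(reference$age_bin))
  streams <- lapply(stats::setNames(gen_ages, gen_ages), function(a) {
    unlist(wp_encode(vocab,
      reference$utterance[reference$age_bin == a]), use.names = FALSE)
  })
  generated <- generate_age_corpus(fit$model, vocab, gen_ages,
                                   config$generation_config, streams,
                                   quiet = quiet)
  put("generated.jsonl", function(p) write_corpus(generated, p))

  # --- stage 5: evaluate
  say("evaluating ", nrow(generated), " generated utterances")
  gen_binned <- bin_by_age(generated)
  eval_tbl <- evaluate_corpora(gen_binned, reference, gold_by_age, config)
  report <- age_trend_report(eval_tbl)
  novelty <- novelty_profile(gen_binned, train_corpus)
  put(file.path("report", "distributions.csv"),
      function(p) readr::write_csv(eval_tbl, p, progress = FALSE))
  put(file.path("report", "effect_sizes.csv"),
      function(p) readr::write_csv(report$by_measure_bin, p,
                                   progress = FALSE))
  put(file.path("report", "measure_summary.csv"),
      function(p) readr::write_csv(report$measure_summary, p,
                                   progress = FALSE))
  put(file.path("report", "novelty.csv"),
      function(p) readr::write_csv(novelty, p, progress = FALSE))

  manifest <- tibble::tibble(
    file = artifacts,
    hash = vapply(artifacts, function(a) {
      rlang::hash(readLines(file.path(out_dir, a), warn = FALSE))
    }, "")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  say("wrote ", length(artifacts), " artifacts to ", out_dir)
  invisible(list(fit = fit, report = report, novelty = novelty,
                 vocab = vocab, out_dir = out_dir,
                 generated = generated, reference = reference))
}

# per-bin resample distributions for the measures computable on both
# sides (the generated side has no dependency trees: lexical measures
# plus mean utterance length)
evaluate_corpora <- function(generated, reference, gold_by_age, config) {
  te <- config$text_eval
  bins <- intersect(unique(generated$age_bin),
                    unique(reference$age_bin))
  mlu_metric <- function(tok) {
    c(mean_utt_len = nrow(tok) / length(unique(tok$utt_id)))
  }
  purrr::map_dfr(bins, function(b) {
    res <- dplyr::bind_rows(
      list(generated = generated[generated$age_bin == b, ],
           reference = reference[reference$age_bin == b, ]) |>
        purrr::imap(function(corp, src) {
          tok <- annotate_pseudo_corpus(corp)
          lex_unit <- min(te$lexical_unit, nrow(tok))
          utt_unit <- min(te$syntactic_unit, length(unique(tok$utt_id)))
          lex <- subsampled_distribution(
            tok, lexical_profile, n_resamples = te$n_resamples,
            unit = "words", unit_size = lex_unit,
            seed = config$rng_seed + b)
          syn <- subsampled_distribution(
            tok, mlu_metric, n_resamples = te$n_resamples,
            unit = "utterances", unit_size = utt_unit,
            seed = config$rng_seed + b + 1L)
          dplyr::bind_cols(lex, syn["mean_utt_len"]) |>
            tidyr::pivot_longer(-".resample", names_to = "metric",
                                values_to = "value") |>
            dplyr::mutate(source = src, age_bin = b)
        }))
    res
  }) |>
    dplyr::select("source", "age_bin", "metric", "value") |>
    # a metric undefined on either side in any bin (e.g. a POS-group TTR
    # with no tokens) cannot be compared; drop it wholesale
    dplyr::group_by(.data$metric) |>
    dplyr::filter(!any(is.na(.data$value))) |>
    dplyr::ungroup()
}
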