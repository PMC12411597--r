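toy_cfg <- function(...) {
  defaults <- list(vocab_size = 23L, embed_dim = 16L, n_blocks = 2L,
                   n_heads = 2L, dropout = 0, seq_len = 12L,
                   age_hidden_dim = 8L, mlp_ratio = 2L, rng_seed = 4L)
  do.call(age_lm_config, utils::modifyList(defaults, list(...)))
}

toy_dataset <- function(n, seq_len = 12L, vocab = 23L, seed = 1,
                        ages = c(6, 48)) {
  withr::with_seed(seed, {
    ids <- matrix(sample.int(vocab, n * seq_len, replace = TRUE) - 1L,
                  n, seq_len)
    cdsgen:::new_training_dataset(ids, sample(ages, n, replace = TRUE),
                                  vocab)
  })
}

test_that("full-scale defaults match the working configuration exactly", {
  cfg <- age_lm_config()
  expect_equal(cfg$vocab_size, 8000L)
  expect_equal(cfg$embed_dim, 512L)
  expect_equal(cfg$n_blocks, 5L)
  expect_equal(cfg$n_heads, 8L)
  expect_equal(cfg$dropout, 0.05)
  expect_equal(cfg$seq_len, 100L)
  expect_equal(cfg$lr, 1e-4)
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$patience, 15L)
})

test_that("invalid configurations are rejected with all violations listed", {
  expect_error(age_lm_config(embed_dim = 30L, n_heads = 8L), "divisible")
  expect_error(age_lm_config(dropout = 1.5), "dropout")
  expect_error(age_lm_config(dropout = 1.5, embed_dim = 30L),
               "divisible.*dropout|dropout.*divisible")
})

test_that("model construction is deterministic and has the requested shape", {
  m1 <- build_age_lm(toy_cfg())
  m2 <- build_age_lm(toy_cfg())
  expect_identical(m1$params, m2$params)
  expect_length(m1$params$blocks, 2L)
  expect_equal(dim(m1$params$wte), c(23L, 16L))
  m3 <- build_age_lm(toy_cfg(rng_seed = 9L))
  expect_false(identical(m1$params$wte, m3$params$wte))
})

test_that("forward returns one probability row per token, each summing to 1", {
  model <- build_age_lm(toy_cfg())
  probs <- age_lm_forward(model, c(0L, 5L, 9L, 2L, 2L, 11L), age = 24)
  expect_equal(dim(probs), c(6L, 23L))
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-5)
  expect_error(age_lm_forward(model, c(0L, 99L), 24), "outside")
  expect_error(age_lm_forward(model, rep(0L, 50), 24), "seq_len")
})

test_that("causal masking: perturbing token j never changes outputs before j", {
  model <- build_age_lm(toy_cfg())
  ids <- c(1L, 4L, 7L, 9L, 3L, 6L, 0L, 2L)
  p0 <- age_lm_forward(model, ids, 24)
  for (j in c(4L, 7L)) {
    ids2 <- ids
    ids2[j] <- (ids2[j] + 5L) %% 23L
    p1 <- age_lm_forward(model, ids2, 24)
    expect_equal(p1[seq_len(j - 1L), ], p0[seq_len(j - 1L), ],
                 tolerance = 1e-10)
    expect_gt(max(abs(p1[j, ] - p0[j, ])), 0)
  }
})

test_that("the age input changes the output distributions", {
  model <- build_age_lm(toy_cfg())
  ids <- c(1L, 4L, 7L)
  p6 <- age_lm_forward(model, ids, 6)
  p48 <- age_lm_forward(model, ids, 48)
  expect_gt(max(abs(p6 - p48)), 0)
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- age_lm_config(vocab_size = 7L, embed_dim = 8L, n_blocks = 2L,
                       n_heads = 2L, dropout = 0, seq_len = 5L,
                       age_hidden_dim = 4L, mlp_ratio = 2L, rng_seed = 2L)
  model <- build_age_lm(cfg)
  ids <- matrix(c(0L, 3L, 6L, 1L, 2L,
                  5L, 5L, 0L, 4L, 1L), 2, 5, byrow = TRUE)
  ages <- c(6, 48)
  res <- cdsgen:::lm_batch(model, ids, ages, grads = TRUE,
                           training = FALSE)
  eps <- 1e-5
  num_grad <- function(path, idx) {
    up <- model
    p <- up$params
    ref <- p
    get_leaf <- function(pp) purrr::pluck(pp, !!!path)
    set_leaf <- function(pp, v) purrr::assign_in(pp, path, v)
    leaf <- get_leaf(p)
    leaf[idx] <- leaf[idx] + eps
    up$params <- set_leaf(p, leaf)
    lp <- cdsgen:::lm_batch(up, ids, ages, grads = FALSE)$loss
    leaf[idx] <- leaf[idx] - 2 * eps
    up$params <- set_leaf(p, leaf)
    lm <- cdsgen:::lm_batch(up, ids, ages, grads = FALSE)$loss
    (lp - lm) / (2 * eps)
  }
  checks <- list(
    list(path = list("wte"), idx = c(4L, 2L)),
    list(path = list("wpe"), idx = c(2L, 3L)),
    list(path = list("age_w1"), idx = c(1L, 2L)),
    list(path = list("age_W2"), idx = c(3L, 5L)),
    list(path = list("blocks", 1L, "Wq"), idx = c(2L, 7L)),
    list(path = list("blocks", 1L, "Wv"), idx = c(5L, 1L)),
    list(path = list("blocks", 2L, "Wo"), idx = c(1L, 4L)),
    list(path = list("blocks", 2L, "W1"), idx = c(3L, 9L)),
    list(path = list("blocks", 1L, "ln1_g"), idx = 3L),
    list(path = list("blocks", 2L, "ln2_b"), idx = 6L),
    list(path = list("lnf_g"), idx = 2L),
    list(path = list("Wout"), idx = c(6L, 3L)),
    list(path = list("bout"), idx = 5L)
  )
  for (ck in checks) {
    ana <- purrr::pluck(res$grads, !!!ck$path)[matrix(ck$idx, 1)]
    if (length(ck$idx) == 1) {
      ana <- purrr::pluck(res$grads, !!!ck$path)[ck$idx]
    }
    num <- num_grad(ck$path, if (length(ck$idx) == 1) ck$idx
                    else matrix(ck$idx, 1))
    expect_equal(ana, num, tolerance = 1e-4,
                 label = paste0("grad ", paste(unlist(ck$path),
                                               collapse = "/")))
  }
})

test_that("uniform predictions give ln(V) cross-entropy; ln(8000) is 8.987 nats", {
  # a freshly built model with zeroed output weights predicts uniformly
  cfg <- toy_cfg()
  model <- build_age_lm(cfg)
  model$params$Wout[] <- 0
  model$params$bout[] <- 0
  ds <- toy_dataset(4L)
  r <- cdsgen:::lm_batch(model, ds$ids, ds$age, grads = FALSE)
  expect_equal(r$loss, log(23), tolerance = 1e-10)
  expect_equal(log(8000), 8.987, tolerance = 1e-3)
})

test_that("an over-parameterized model memorizes a tiny repeated dataset", {
  cfg <- age_lm_config(vocab_size = 17L, embed_dim = 32L, n_blocks = 2L,
                       n_heads = 4L, dropout = 0, seq_len = 8L,
                       age_hidden_dim = 8L, mlp_ratio = 2L, lr = 3e-3,
                       batch_size = 32L, patience = 300L,
                       max_epochs = 200L, rng_seed = 3L)
  model <- build_age_lm(cfg)
  base <- matrix(c(3L, 14L, 7L, 0L, 9L, 2L, 11L, 5L), 1)
  train <- cdsgen:::new_training_dataset(
    base[rep(1L, 64L), , drop = FALSE], rep(24, 64L), 17L)
  fit <- train_age_lm(model, train, train, quiet = TRUE)
  expect_lt(min(fit$history$train_loss), 0.1)
})

test_that("early stopping triggers after `patience` non-improving epochs and keeps the best model", {
  cfg <- toy_cfg(patience = 3L, max_epochs = 50L, lr = 0.05,
                 batch_size = 16L)
  model <- build_age_lm(cfg)
  train <- toy_dataset(32L, seed = 5)
  valid <- toy_dataset(8L, seed = 6)
  fit <- train_age_lm(model, train, valid, quiet = TRUE)
  h <- fit$history
  expect_equal(fit$best_epoch, which.min(h$valid_loss))
  expect_lte(fit$best_valid_loss, min(h$valid_loss))
  if (fit$stopped_early) {
    expect_equal(nrow(h), fit$best_epoch + cfg$patience)
  }
  # the returned model reproduces the best validation loss
  revalid <- cdsgen:::lm_batch(fit$model, valid$ids, valid$age,
                               grads = FALSE)
  expect_equal(revalid$loss, fit$best_valid_loss, tolerance = 1e-10)
  expect_equal(glance(fit)$best_epoch, fit$best_epoch)
  expect_equal(nrow(tidy(fit)), nrow(h))
})

test_that("training is deterministic given the seed", {
  cfg <- toy_cfg(max_epochs = 2L, patience = 5L, batch_size = 16L,
                 dropout = 0.1)
  train <- toy_dataset(24L, seed = 8)
  valid <- toy_dataset(8L, seed = 9)
  f1 <- train_age_lm(build_age_lm(cfg), train, valid, quiet = TRUE)
  f2 <- train_age_lm(build_age_lm(cfg), train, valid, quiet = TRUE)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("checkpoints round-trip parameters, config and vocabulary hash", {
  model <- build_age_lm(toy_cfg())
  vocab <- train_subword_vocab(vocab_corpus(100), size = 60L)
  path <- withr::local_tempfile(fileext = ".json")
  write_age_lm(model, path, vocab)
  back <- read_age_lm(path, vocab)
  expect_equal(back$params, model$params, tolerance = 1e-12)
  expect_equal(unclass(back$config), unclass(model$config))
  p1 <- age_lm_forward(model, c(1L, 2L, 3L), 24)
  p2 <- age_lm_forward(back, c(1L, 2L, 3L), 24)
  expect_equal(p1, p2, tolerance = 1e-12)
  other <- train_subword_vocab(vocab_corpus(100, seed = 9), size = 55L)
  expect_error(read_age_lm(path, other), "different vocabulary")
})
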