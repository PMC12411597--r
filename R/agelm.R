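#' Configuration of the age-conditioned language model
#'
#' A decoder-only transformer over WordPiece tokens with scalar-age
#' conditioning: token and learned positional embeddings are summed, the
#' child age in months is scaled by `age_scale`, passed through a one
#' hidden-layer ReLU encoder to an `embed_dim` vector, and that age
#' vector is prepended to the token sequence (it receives no positional
#' embedding and no loss). Causally masked self-attention blocks follow,
#' then a softmax over the vocabulary.
#'
#' The defaults are the full-scale working configuration: vocabulary
#' 8,000, five 512-dimensional blocks with eight heads, dropout 0.05,
#' 100-token inputs, Adam with learning rate 1e-4, minibatches of 64 and
#' early-stopping patience 15.
#'
#' @param vocab_size Vocabulary size.
#' @param embed_dim Model width (divisible by `n_heads`).
#' @param n_blocks Number of transformer blocks.
#' @param n_heads Attention heads.
#' @param dropout Dropout rate on the residual branches, in `[0, 1)`.
#' @param seq_len Token positions (the age vector adds one more).
#' @param age_hidden_dim Hidden width of the age encoder.
#' @param mlp_ratio Feed-forward width multiplier.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs).
#' @param max_epochs Hard epoch cap.
#' @param age_scale Age divisor before the age encoder (months).
#' @param rng_seed Seed for initialization, shuffling and dropout.
#' @return An object of class `age_lm_config`.
#' @export
age_lm_config <- function(vocab_size = 8000L, embed_dim = 512L,
                          n_blocks = 5L, n_heads = 8L, dropout = 0.05,
                          seq_len = 100L, age_hidden_dim = embed_dim,
                          mlp_ratio = 4L, lr = 1e-4, batch_size = 64L,
                          patience = 15L, max_epochs = 500L,
                          age_scale = 84, rng_seed = 1L) {
  cfg <- list(vocab_size = as.integer(vocab_size),
              embed_dim = as.integer(embed_dim),
              n_blocks = as.integer(n_blocks),
              n_heads = as.integer(n_heads),
              dropout = dropout, seq_len = as.integer(seq_len),
              age_hidden_dim = as.integer(age_hidden_dim),
              mlp_ratio = as.integer(mlp_ratio), lr = lr,
              batch_size = as.integer(batch_size),
              patience = as.integer(patience),
              max_epochs = as.integer(max_epochs),
              age_scale = age_scale, rng_seed = as.integer(rng_seed))
  problems <- character(0)
  if (cfg$embed_dim %% cfg$n_heads != 0) {
    problems <- c(problems, "embed_dim must be divisible by n_heads")
  }
  if (cfg$dropout < 0 || cfg$dropout >= 1) {
    problems <- c(problems, "dropout must be in [0, 1)")
  }
  for (f in c("vocab_size", "embed_dim", "n_blocks", "n_heads", "seq_len",
              "age_hidden_dim", "batch_size", "patience")) {
    if (cfg[[f]] <= 0) problems <- c(problems, paste(f, "must be positive"))
  }
  if (cfg$lr <= 0) problems <- c(problems, "lr must be positive")
  if (length(problems)) {
    stop(paste(problems, collapse = "; "), call. = FALSE)
  }
  structure(cfg, class = "age_lm_config")
}

rmat <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)
}

#' Build an age-conditioned language model
#'
#' Initializes all parameters deterministically from
#' `config$rng_seed` (weights N(0, 0.02), zero biases, unit layer-norm
#' gains).
#'
#' @param config An [age_lm_config()].
#' @return An object of class `age_lm` (parameter list + config).
#' @export
build_age_lm <- function(config) {
  stopifnot(inherits(config, "age_lm_config"))
  D <- config$embed_dim
  V <- config$vocab_size
  H <- config$age_hidden_dim
  Ff <- D * config$mlp_ratio
  params <- withr::with_seed(config$rng_seed, {
    blocks <- lapply(seq_len(config$n_blocks), function(l) {
      list(ln1_g = rep(1, D), ln1_b = rep(0, D),
           Wq = rmat(D, D), bq = rep(0, D),
           Wk = rmat(D, D), bk = rep(0, D),
           Wv = rmat(D, D), bv = rep(0, D),
           Wo = rmat(D, D), bo = rep(0, D),
           ln2_g = rep(1, D), ln2_b = rep(0, D),
           W1 = rmat(D, Ff), b1 = rep(0, Ff),
           W2 = rmat(Ff, D), b2 = rep(0, D))
    })
    list(wte = rmat(V, D), wpe = rmat(config$seq_len, D),
         age_w1 = rmat(1, H), age_b1 = rep(0, H),
         age_W2 = rmat(H, D), age_b2 = rep(0, D),
         blocks = blocks,
         lnf_g = rep(1, D), lnf_b = rep(0, D),
         Wout = rmat(D, V), bout = rep(0, V))
  })
  structure(list(params = params, config = config), class = "age_lm")
}

#' @export
print.age_lm <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(rapply(x$params, length, how = "unlist"))
  cat("<age_lm> ", cfg$n_blocks, " blocks, dim ", cfg$embed_dim, ", ",
      cfg$n_heads, " heads, vocab ", cfg$vocab_size, " (",
      format(n_par, big.mark = ","), " parameters)\n", sep = "")
  invisible(x)
}

layernorm_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  xc <- X - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * inv
  list(Y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(X)),
       xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dyh <- sweep(dY, 2, g, "*")
  m1 <- rowMeans(dyh)
  m2 <- rowMeans(dyh * xhat)
  dX <- cache$inv * (dyh - m1 - xhat * m2)
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

gelu_fwd <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

# Forward (and optionally backward) pass over a minibatch.
# ids: B x T matrix of 0-based token ids; ages: length-B months.
# Returns loss (mean next-token cross-entropy, nats), gradients mirroring
# the parameter structure, and optionally the full output distributions.
lm_batch <- function(model, ids, ages, grads = TRUE, training = grads,
                     want_probs = FALSE, loss_positions = NULL) {
  params <- model$params
  cfg <- model$config
  B <- nrow(ids)
  T_ <- ncol(ids)
  S <- T_ + 1L
  D <- cfg$embed_dim
  nh <- cfg$n_heads
  dh <- D %/% nh
  N <- B * S
  s_of_row <- rep(seq_len(S), B)
  tok_rows <- which(s_of_row != 1L)
  ids_vec <- as.integer(t(ids))

  # --- embeddings
  a_in <- ages / cfg$age_scale
  h1_pre <- outer(a_in, params$age_w1[1, ]) +
    rep(params$age_b1, each = B)
  h1 <- pmax(h1_pre, 0)
  age_vec <- h1 %*% params$age_W2 + rep(params$age_b2, each = B)
  X <- matrix(0, N, D)
  pos_idx <- rep(seq_len(T_), B)
  X[tok_rows, ] <- params$wte[ids_vec + 1L, , drop = FALSE] +
    params$wpe[pos_idx, , drop = FALSE]
  X[s_of_row == 1L, ] <- age_vec

  keep_p <- 1 - cfg$dropout
  caches <- vector("list", cfg$n_blocks)
  mask <- lower.tri(matrix(TRUE, S, S), diag = TRUE)

  for (l in seq_len(cfg$n_blocks)) {
    bl <- params$blocks[[l]]
    ln1 <- layernorm_fwd(X, bl$ln1_g, bl$ln1_b)
    Q <- ln1$Y %*% bl$Wq + rep(bl$bq, each = N)
    K <- ln1$Y %*% bl$Wk + rep(bl$bk, each = N)
    Vv <- ln1$Y %*% bl$Wv + rep(bl$bv, each = N)
    O <- matrix(0, N, D)
    A_list <- if (grads) vector("list", B * nh)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S + 1L):(b * S)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        Qh <- Q[rows, cols, drop = FALSE]
        Kh <- K[rows, cols, drop = FALSE]
        Sc <- tcrossprod(Qh, Kh) / sqrt(dh)
        Sc[!mask] <- -Inf
        Sc <- Sc - apply(Sc, 1, max)
        E <- exp(Sc)
        A <- E / rowSums(E)
        O[rows, cols] <- A %*% Vv[rows, cols, drop = FALSE]
        if (grads) A_list[[(b - 1L) * nh + h]] <- A
      }
    }
    Aout <- O %*% bl$Wo + rep(bl$bo, each = N)
    drop1 <- NULL
    if (training && cfg$dropout > 0) {
      drop1 <- matrix(stats::rbinom(N * D, 1L, keep_p) / keep_p, N, D)
      Aout <- Aout * drop1
    }
    X1 <- X + Aout
    ln2 <- layernorm_fwd(X1, bl$ln2_g, bl$ln2_b)
    M_pre <- ln2$Y %*% bl$W1 + rep(bl$b1, each = N)
    M <- gelu_fwd(M_pre)
    M2 <- M %*% bl$W2 + rep(bl$b2, each = N)
    drop2 <- NULL
    if (training && cfg$dropout > 0) {
      drop2 <- matrix(stats::rbinom(N * D, 1L, keep_p) / keep_p, N, D)
      M2 <- M2 * drop2
    }
    Xnew <- X1 + M2
    if (grads) {
      caches[[l]] <- list(ln1 = ln1, Q = Q, K = K, V = Vv, O = O,
                          A_list = A_list, drop1 = drop1, X1 = X1,
                          ln2 = ln2, M_pre = M_pre, M = M, drop2 = drop2)
    }
    X <- Xnew
  }
  lnf <- layernorm_fwd(X, params$lnf_g, params$lnf_b)
  Hf <- lnf$Y

  # loss rows: token position i (1-based) predicts token i+1; the age
  # position (s = 1) and the last token carry no loss
  if (is.null(loss_positions)) loss_positions <- seq_len(T_ - 1L)
  loss_positions <- loss_positions[loss_positions < T_]
  sel <- which((s_of_row - 1L) %in% loss_positions)
  loss <- NA_real_
  if (length(sel) > 0) {
    targ_col <- s_of_row[sel]  # 0-based target id lives at ids[, s]
    b_of_sel <- (sel - 1L) %/% S + 1L
    targets <- ids[cbind(b_of_sel, targ_col)]
    logits <- Hf[sel, , drop = FALSE] %*% params$Wout +
      rep(params$bout, each = length(sel))
    logits <- logits - apply(logits, 1, max)
    P <- exp(logits)
    P <- P / rowSums(P)
    nl <- length(sel)
    loss <- -mean(log(P[cbind(seq_len(nl), targets + 1L)]))
  }

  out <- list(loss = loss)
  if (want_probs) {
    all_logits <- Hf %*% params$Wout + rep(params$bout, each = N)
    all_logits <- all_logits - apply(all_logits, 1, max)
    PA <- exp(all_logits)
    out$probs <- PA / rowSums(PA)   # row (b-1)*S + s
    out$s_of_row <- s_of_row
  }
  if (!grads) return(out)
  if (length(sel) == 0) {
    stop("no loss positions: sequences must have at least 2 tokens",
         call. = FALSE)
  }

  # --- backward
  g <- list()
  dlogits <- P
  dlogits[cbind(seq_len(nl), targets + 1L)] <-
    dlogits[cbind(seq_len(nl), targets + 1L)] - 1
  dlogits <- dlogits / nl
  g$Wout <- crossprod(Hf[sel, , drop = FALSE], dlogits)
  g$bout <- colSums(dlogits)
  dHf <- matrix(0, N, D)
  dHf[sel, ] <- dlogits %*% t(params$Wout)
  lb <- layernorm_bwd(dHf, lnf, params$lnf_g)
  g$lnf_g <- lb$dg
  g$lnf_b <- lb$db
  dX <- lb$dX

  g$blocks <- vector("list", cfg$n_blocks)
  for (l in rev(seq_len(cfg$n_blocks))) {
    bl <- params$blocks[[l]]
    ca <- caches[[l]]
    gb <- list()
    dM2 <- if (!is.null(ca$drop2)) dX * ca$drop2 else dX
    gb$W2 <- crossprod(ca$M, dM2)
    gb$b2 <- colSums(dM2)
    dM <- dM2 %*% t(bl$W2)
    dM_pre <- dM * gelu_grad(ca$M_pre)
    gb$W1 <- crossprod(ca$ln2$Y, dM_pre)
    gb$b1 <- colSums(dM_pre)
    dZ <- dM_pre %*% t(bl$W1)
    lb2 <- layernorm_bwd(dZ, ca$ln2, bl$ln2_g)
    gb$ln2_g <- lb2$dg
    gb$ln2_b <- lb2$db
    dX1 <- dX + lb2$dX
    dAout <- if (!is.null(ca$drop1)) dX1 * ca$drop1 else dX1
    gb$Wo <- crossprod(ca$O, dAout)
    gb$bo <- colSums(dAout)
    dO <- dAout %*% t(bl$Wo)
    dQ <- matrix(0, N, D)
    dK <- matrix(0, N, D)
    dV <- matrix(0, N, D)
    for (b in seq_len(B)) {
      rows <- ((b - 1L) * S + 1L):(b * S)
      for (h in seq_len(nh)) {
        cols <- ((h - 1L) * dh + 1L):(h * dh)
        A <- ca$A_list[[(b - 1L) * nh + h]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- ca$V[rows, cols, drop = FALSE]
        dA <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(A, dOh)
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        dQ[rows, cols] <- dS %*% ca$K[rows, cols, drop = FALSE]
        dK[rows, cols] <- crossprod(dS, ca$Q[rows, cols, drop = FALSE])
      }
    }
    gb$Wq <- crossprod(ca$ln1$Y, dQ)
    gb$bq <- colSums(dQ)
    gb$Wk <- crossprod(ca$ln1$Y, dK)
    gb$bk <- colSums(dK)
    gb$Wv <- crossprod(ca$ln1$Y, dV)
    gb$bv <- colSums(dV)
    dY <- dQ %*% t(bl$Wq) + dK %*% t(bl$Wk) + dV %*% t(bl$Wv)
    lb1 <- layernorm_bwd(dY, ca$ln1, bl$ln1_g)
    gb$ln1_g <- lb1$dg
    gb$ln1_b <- lb1$db
    dX <- dX1 + lb1$dX
    g$blocks[[l]] <- gb
  }

  # embeddings
  dtok <- dX[tok_rows, , drop = FALSE]
  g$wte <- rowsum(dtok, ids_vec, reorder = FALSE)
  # rowsum groups by first occurrence; map back onto the full table
  wte_grad <- matrix(0, cfg$vocab_size, D)
  wte_grad[as.integer(rownames(g$wte)) + 1L, ] <- g$wte
  g$wte <- wte_grad
  wpe_grad <- rowsum(dtok, pos_idx, reorder = TRUE)
  g$wpe <- matrix(0, cfg$seq_len, D)
  g$wpe[as.integer(rownames(wpe_grad)), ] <- wpe_grad
  dage <- dX[s_of_row == 1L, , drop = FALSE]
  g$age_W2 <- crossprod(h1, dage)
  g$age_b2 <- colSums(dage)
  dh1 <- (dage %*% t(params$age_W2)) * (h1_pre > 0)
  g$age_w1 <- matrix(colSums(dh1 * a_in), 1)
  g$age_b1 <- colSums(dh1)
  out$grads <- g
  out
}

#' Next-token distributions for one token sequence
#'
#' Runs the model on a single id sequence under a conditioning age and
#' returns the next-token probability distribution at every token
#' position (causally masked: the distribution at position `t` depends
#' only on tokens 1..t and the age). The prepended age position's output
#' is not returned.
#'
#' @param model An `age_lm`.
#' @param token_ids Integer vector of 0-based token ids (length <=
#'   `seq_len`).
#' @param age Conditioning age in months.
#' @return A matrix `length(token_ids)` x `vocab_size`; each row sums
#'   to 1.
#' @export
age_lm_forward <- function(model, token_ids, age) {
  cfg <- model$config
  token_ids <- as.integer(token_ids)
  if (any(token_ids < 0L | token_ids >= cfg$vocab_size)) {
    stop("token id outside the vocabulary", call. = FALSE)
  }
  if (length(token_ids) > cfg$seq_len) {
    stop("sequence longer than seq_len", call. = FALSE)
  }
  res <- lm_batch(model, matrix(token_ids, nrow = 1), age,
                  grads = FALSE, training = FALSE, want_probs = TRUE,
                  loss_positions = 1L)
  # rows 2..S are the token positions
  res$probs[res$s_of_row != 1L, , drop = FALSE]
}

# elementwise map over the nested parameter structure
param_map <- function(f, ...) {
  args <- list(...)
  rec <- function(...) {
    xs <- list(...)
    if (is.list(xs[[1]])) {
      out <- vector("list", length(xs[[1]]))
      nm <- names(xs[[1]])
      names(out) <- nm
      for (i in seq_along(out)) {
        # align by name where available: parallel structures may order
        # their fields differently
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else i
        out[[i]] <- do.call(rec, lapply(xs, `[[`, key))
      }
      out
    } else {
      do.call(f, xs)
    }
  }
  do.call(rec, args)
}

#' Train the age-conditioned language model
#'
#' Minibatch Adam on the mean next-token cross-entropy (nats), with
#' per-epoch shuffling, validation after every epoch, and early stopping
#' when the validation loss has not improved for `patience` consecutive
#' epochs; the best (lowest validation loss) parameters are returned.
#' All randomness (shuffling, dropout) derives from `config$rng_seed`.
#'
#' @param model An `age_lm` from [build_age_lm()].
#' @param train,valid `training_dataset` objects (see
#'   [make_training_samples()]).
#' @param quiet Suppress per-epoch messages.
#' @return An object of class `age_lm_fit`: `model` (best parameters),
#'   `history` (per-epoch train/valid loss tibble), `best_epoch`,
#'   `stopped_early`.
#' @export
train_age_lm <- function(model, train, valid, quiet = FALSE) {
  stopifnot(inherits(model, "age_lm"),
            inherits(train, "training_dataset"),
            inherits(valid, "training_dataset"))
  if (train$n == 0 || valid$n == 0) {
    stop("empty training or validation dataset", call. = FALSE)
  }
  cfg <- model$config
  adam_m <- param_map(function(p) p * 0, model$params)
  adam_v <- adam_m
  beta1 <- 0.9
  beta2 <- 0.999
  eps <- 1e-8
  step <- 0L
  best_params <- model$params
  best_loss <- Inf
  best_epoch <- 0L
  bad_epochs <- 0L
  hist <- list()
  stopped_early <- FALSE

  valid_loss <- function(m) {
    tot <- 0
    n <- 0
    i <- 1L
    while (i <= valid$n) {
      j <- min(i + cfg$batch_size - 1L, valid$n)
      r <- lm_batch(m, valid$ids[i:j, , drop = FALSE], valid$age[i:j],
                    grads = FALSE, training = FALSE)
      tot <- tot + r$loss * (j - i + 1L)
      n <- n + (j - i + 1L)
      i <- j + 1L
    }
    tot / n
  }

  withr::with_seed(cfg$rng_seed + 1L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(train$n)
      tr_tot <- 0
      i <- 1L
      while (i <= train$n) {
        j <- min(i + cfg$batch_size - 1L, train$n)
        idx <- ord[i:j]
        res <- lm_batch(model, train$ids[idx, , drop = FALSE],
                        train$age[idx], grads = TRUE, training = TRUE)
        if (!is.finite(res$loss)) {
          stop("training diverged: non-finite loss at epoch ", epoch,
               call. = FALSE)
        }
        tr_tot <- tr_tot + res$loss * length(idx)
        step <- step + 1L
        lr_t <- cfg$lr * sqrt(1 - beta2^step) / (1 - beta1^step)
        adam_m <- param_map(function(m, gr) beta1 * m + (1 - beta1) * gr,
                            adam_m, res$grads)
        adam_v <- param_map(function(v, gr) beta2 * v +
                              (1 - beta2) * gr * gr,
                            adam_v, res$grads)
        model$params <- param_map(
          function(p, m, v) p - lr_t * m / (sqrt(v) + eps),
          model$params, adam_m, adam_v)
        i <- j + 1L
      }
      tl <- tr_tot / train$n
      vl <- valid_loss(model)
      hist[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = tl,
                                      valid_loss = vl)
      if (!quiet) {
        message(sprintf("epoch %3d  train %.4f  valid %.4f", epoch, tl, vl))
      }
      if (vl < best_loss) {
        best_loss <- vl
        best_params <- model$params
        best_epoch <- epoch
        bad_epochs <- 0L
      } else {
        bad_epochs <- bad_epochs + 1L
        if (bad_epochs >= cfg$patience) {
          stopped_early <- TRUE
          break
        }
      }
    }
  })
  model$params <- best_params
  structure(list(model = model,
                 history = dplyr::bind_rows(hist),
                 best_epoch = best_epoch,
                 best_valid_loss = best_loss,
                 stopped_early = stopped_early),
            class = "age_lm_fit")
}

#' @export
print.age_lm_fit <- function(x, ...) {
  cat("<age_lm_fit> ", nrow(x$history), " epochs; best epoch ",
      x$best_epoch, " (valid loss ", round(x$best_valid_loss, 4), ")",
      if (x$stopped_early) "; stopped early", "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x An `age_lm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per epoch: `epoch`, `train_loss`,
#'   `valid_loss` (mean token cross-entropy, nats).
#' @export
tidy.age_lm_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x An `age_lm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `epochs`, `best_epoch`, `best_valid_loss`,
#'   `final_train_loss`, `stopped_early`, `n_parameters`.
#' @export
glance.age_lm_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_valid_loss = x$best_valid_loss,
    final_train_loss = x$history$train_loss[nrow(x$history)],
    stopped_early = x$stopped_early,
    n_parameters = sum(rapply(x$model$params, length, how = "unlist"))
  )
}

#' Plot training and validation loss curves
#'
#' @param object An `age_lm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.age_lm_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
                              names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(y = "cross-entropy (nats)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Save / load a model checkpoint
#'
#' Single-file JSON checkpoint carrying the configuration, all
#' parameters, and a hash of the vocabulary it was trained against, so
#' generation is reproducible against the exact vocabulary.
#'
#' @param model An `age_lm`.
#' @param path Checkpoint path.
#' @param vocab The `wordpiece_vocab` used for training (hashed into the
#'   checkpoint).
#' @export
write_age_lm <- function(model, path, vocab = NULL) {
  ck <- list(
    config = unclass(model$config),
    vocab_hash = if (!is.null(vocab)) {
      rlang::hash(vocab$pieces)
    },
    params = rapply(model$params, function(p) {
      list(dim = dim(p), data = as.numeric(p))
    }, how = "list")
  )
  jsonlite::write_json(ck, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_age_lm
#' @export
read_age_lm <- function(path, vocab = NULL) {
  ck <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE)
  if (!is.null(vocab) && !is.null(ck$vocab_hash) &&
      !identical(ck$vocab_hash, rlang::hash(vocab$pieces))) {
    stop("checkpoint was trained against a different vocabulary",
         call. = FALSE)
  }
  cfg <- do.call(age_lm_config, ck$config[setdiff(names(ck$config), NULL)])
  restore <- function(x) {
    if (is.list(x) && identical(sort(names(x)), c("data", "dim"))) {
      if (is.null(x$dim) || length(x$dim) == 0) {
        as.numeric(x$data)
      } else {
        matrix(as.numeric(x$data), x$dim[1], x$dim[2])
      }
    } else if (is.list(x)) {
      lapply(x, restore)
    } else {
      x
    }
  }
  structure(list(params = restore(ck$params), config = cfg),
            class = "age_lm")
}
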