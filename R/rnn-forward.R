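# Batched forward dynamics for the three recurrent unit types.
#
# Sequences are processed as an integer matrix S (B sequences x T steps,
# values 1..4 in alphabet order A,C,G,T). At step t the input is the one-hot
# encoding of symbol t-1; the first step receives the all-zero
# begin-of-sequence vector, so p(s_1) comes from the zero initial state. The
# output at step t is the softmax distribution over symbol t.
#
# One-hot algebra is done by column indexing: W %*% onehot(k) == W[, k].

rnn_forward <- function(params, S, keep_cache = FALSE, keep_probs = FALSE) {
  spec <- attr(params, "spec")
  H <- spec$hidden
  B <- nrow(S)
  T_ <- ncol(S)
  type <- spec$unit_type
  h <- matrix(0, H, B)
  cs <- if (type == "lstm") matrix(0, H, B)  # lstm cell state
  cache <- if (keep_cache) vector("list", T_)
  probs <- if (keep_probs) vector("list", T_)
  target_lp <- matrix(0, T_, B)
  ones <- rep(1, B)

  for (t in seq_len(T_)) {
    prev <- if (t > 1L) S[, t - 1L] else NULL
    h_prev <- h
    if (type == "rnn") {
      a <- params$U %*% h_prev + params$b[, ones, drop = FALSE]
      if (!is.null(prev)) a <- a + params$W[, prev, drop = FALSE]
      h <- tanh(a)
      if (keep_cache) cache[[t]] <- list(h = h, h_prev = h_prev)
    } else if (type == "gru") {
      az <- params$Uz %*% h_prev + (params$bz + params$dz)[, ones, drop = FALSE]
      ar <- params$Ur %*% h_prev + (params$br + params$dr)[, ones, drop = FALSE]
      if (!is.null(prev)) {
        az <- az + params$Wz[, prev, drop = FALSE]
        ar <- ar + params$Wr[, prev, drop = FALSE]
      }
      z <- sigmoid(az)
      r <- sigmoid(ar)
      rh <- r * h_prev
      ah <- params$Uh %*% rh + (params$bh + params$dh)[, ones, drop = FALSE]
      if (!is.null(prev)) ah <- ah + params$Wh[, prev, drop = FALSE]
      hc <- tanh(ah)
      h <- (1 - z) * hc + z * h_prev
      if (keep_cache)
        cache[[t]] <- list(h = h, h_prev = h_prev, z = z, r = r, hc = hc, rh = rh)
    } else { # lstm
      pre <- function(W, U, b, d) {
        a <- U %*% h_prev + (b + d)[, ones, drop = FALSE]
        if (!is.null(prev)) a <- a + W[, prev, drop = FALSE]
        a
      }
      gi <- sigmoid(pre(params$Wi, params$Ui, params$bi, params$di))
      gf <- sigmoid(pre(params$Wf, params$Uf, params$bf, params$df))
      go <- sigmoid(pre(params$Wo, params$Uo, params$bo, params$do))
      gg <- tanh(pre(params$Wg, params$Ug, params$bg, params$dg))
      c_prev <- cs
      cs <- gf * c_prev + gi * gg
      tc <- tanh(cs)
      h <- go * tc
      if (keep_cache)
        cache[[t]] <- list(h = h, h_prev = h_prev, i = gi, f = gf, o = go,
                           g = gg, c = cs, c_prev = c_prev, tc = tc)
    }
    logits <- params$V %*% h + params$c[, ones, drop = FALSE]
    lp <- log_softmax_cols(logits)
    target_lp[t, ] <- lp[cbind(S[, t], seq_len(B))]
    if (keep_cache) cache[[t]]$p <- exp(lp)
    if (keep_probs) probs[[t]] <- exp(lp)
  }
  list(target_lp = target_lp, cache = cache, probs = probs)
}

resolve_params <- function(model) {
  if (inherits(model, "rnn_model")) model$params
  else if (inherits(model, "rnn_params")) model
  else stop_fmt("expected an `rnn_model` or `rnn_params` object")
}

# Run forward over possibly many sequences in bounded-memory chunks;
# fn(target_lp, probs_or_null, S_chunk) is called per chunk.
forward_chunked <- function(params, seqs, keep_probs, fn, chunk = 8192L) {
  S <- seq_to_int(seqs)
  n <- nrow(S)
  starts <- seq(1L, n, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, n)
    fw <- rnn_forward(params, S[idx, , drop = FALSE], keep_probs = keep_probs)
    fn(fw$target_lp, fw$probs, S[idx, , drop = FALSE], idx)
  }
  invisible(NULL)
}

#' One recurrent step
#'
#' Advances a single model state by one time step. For the vanilla unit
#' `h_t = tanh(W s_t + U h_{t-1} + b)`; the GRU uses update/reset gates and
#' the LSTM input/forget/output gates with a linear cell-state pathway.
#'
#' @param params An `rnn_params` object (see [init_params()]).
#' @param s_t Input vector of length 4: a one-hot base encoding, or all zeros
#'   for the begin-of-sequence step.
#' @param state Previous state: numeric vector `h` of length `hidden` for
#'   `rnn`/`gru`, or `list(h =, c =)` for `lstm`. `NULL` means the zero state.
#' @return New state in the same shape as `state`.
#' @export
cell_forward <- function(params, s_t, state = NULL) {
  spec <- attr(params, "spec")
  if (length(s_t) != 4L || !is.numeric(s_t))
    stop_fmt("`s_t` must be a numeric vector of length 4")
  H <- spec$hidden
  if (is.null(state)) {
    state <- if (spec$unit_type == "lstm") list(h = numeric(H), c = numeric(H))
             else numeric(H)
  }
  x <- matrix(s_t, 4L, 1L)
  if (spec$unit_type == "lstm") {
    if (!is.list(state) || length(state$h) != H || length(state$c) != H)
      stop_fmt("lstm state must be list(h, c) with vectors of length %d", H)
    h_prev <- matrix(state$h, H, 1L)
    c_prev <- matrix(state$c, H, 1L)
    gi <- sigmoid(params$Wi %*% x + params$Ui %*% h_prev + params$bi + params$di)
    gf <- sigmoid(params$Wf %*% x + params$Uf %*% h_prev + params$bf + params$df)
    go <- sigmoid(params$Wo %*% x + params$Uo %*% h_prev + params$bo + params$do)
    gg <- tanh(params$Wg %*% x + params$Ug %*% h_prev + params$bg + params$dg)
    cc <- gf * c_prev + gi * gg
    list(h = as.numeric(go * tanh(cc)), c = as.numeric(cc))
  } else if (spec$unit_type == "gru") {
    if (length(state) != H) stop_fmt("state must have length %d", H)
    h_prev <- matrix(state, H, 1L)
    z <- sigmoid(params$Wz %*% x + params$Uz %*% h_prev + params$bz + params$dz)
    r <- sigmoid(params$Wr %*% x + params$Ur %*% h_prev + params$br + params$dr)
    hc <- tanh(params$Wh %*% x + params$Uh %*% (r * h_prev) + params$bh + params$dh)
    as.numeric((1 - z) * hc + z * h_prev)
  } else {
    if (length(state) != H) stop_fmt("state must have length %d", H)
    as.numeric(tanh(params$W %*% x + params$U %*% matrix(state, H, 1L) + params$b))
  }
}

#' Next-symbol output distribution
#'
#' Applies the softmax output layer to a hidden state:
#' `softmax(V h_t + c)`, a probability vector over A, C, G, T.
#'
#' @param params An `rnn_params` object.
#' @param h_t Hidden state vector (for LSTM, the `h` component).
#' @return Numeric probability 4-vector named A, C, G, T.
#' @export
output_distribution <- function(params, h_t) {
  spec <- attr(params, "spec")
  if (is.list(h_t)) h_t <- h_t$h
  if (length(h_t) != spec$hidden) stop_fmt("`h_t` must have length %d", spec$hidden)
  lp <- log_softmax_cols(params$V %*% matrix(h_t, spec$hidden, 1L) + params$c)
  stats::setNames(as.numeric(exp(lp)), DNA_ALPHABET)
}

#' Log-probability of nucleotide sequences under a model
#'
#' The sequence probability factorises by the chain rule,
#' `p(S) = p(s_1) * prod_t p(s_t | s_1..s_{t-1})`, each conditional coming
#' from the softmax output at the corresponding step; `p(s_1)` is produced
#' from the zero initial state and the all-zero begin-of-sequence input.
#'
#' @param model An `rnn_model` (see [train_model()]) or `rnn_params` object.
#' @param seqs Character vector of equal-length sequences over {A,C,G,T}.
#' @return Numeric vector of natural-log probabilities (each <= 0).
#' @export
sequence_log_probs <- function(model, seqs) {
  params <- resolve_params(model)
  out <- numeric(length(seqs))
  forward_chunked(params, seqs, FALSE, function(tlp, probs, S, idx) {
    out[idx] <<- colSums(tlp)
  })
  out
}

#' @rdname sequence_log_probs
#' @param seq A single sequence.
#' @export
sequence_log_prob <- function(model, seq) {
  stopifnot(length(seq) == 1L)
  sequence_log_probs(model, seq)
}

#' Per-position predictive distributions
#'
#' @param model An `rnn_model` or `rnn_params` object.
#' @param seqs Character vector of equal-length sequences.
#' @return Array of dimension `(n_sequences, length, 4)`; entry `[i, t, a]`
#'   is the model's probability of base `a` at position `t` of sequence `i`
#'   given the preceding symbols.
#' @export
predictive_probs <- function(model, seqs) {
  params <- resolve_params(model)
  T_ <- unique(nchar(seqs))[1L]
  out <- array(NA_real_, dim = c(length(seqs), T_, 4L),
               dimnames = list(NULL, NULL, DNA_ALPHABET))
  forward_chunked(params, seqs, TRUE, function(tlp, probs, S, idx) {
    for (t in seq_len(T_)) out[idx, t, ] <<- t(probs[[t]])
  })
  out
}

#' Per-symbol perplexity of a sequence set
#'
#' `2 ^ (-(1/M) * sum log2 p(s_t | .))` where M is the total number of symbol
#' positions across all sequences. A model that predicts uniformly over the
#' four bases has perplexity exactly 4, the chance level.
#'
#' @inheritParams sequence_log_probs
#' @return Perplexity (>= 1).
#' @export
perplexity <- function(model, seqs) {
  if (length(seqs) == 0L) stop_fmt("`seqs` must be non-empty")
  params <- resolve_params(model)
  total_nll <- 0
  M <- 0L
  forward_chunked(params, seqs, FALSE, function(tlp, probs, S, idx) {
    total_nll <<- total_nll - sum(tlp)
    M <<- M + length(tlp)
  })
  2^(total_nll / (M * log(2)))
}

#' Next-symbol prediction error rate
#'
#' Fraction of symbol positions (over all sequences and all steps) at which
#' the most probable predicted base differs from the observed base. Ties are
#' broken deterministically in alphabet order A < C < G < T. Used for model
#' selection on validation data.
#'
#' @inheritParams sequence_log_probs
#' @return Error rate in [0, 1].
#' @export
prediction_error_rate <- function(model, seqs) {
  if (length(seqs) == 0L) stop_fmt("`seqs` must be non-empty")
  params <- resolve_params(model)
  wrong <- 0L
  M <- 0L
  forward_chunked(params, seqs, TRUE, function(tlp, probs, S, idx) {
    for (t in seq_along(probs)) {
      pred <- max.col(t(probs[[t]]), ties.method = "first")
      wrong <<- wrong + sum(pred != S[, t])
    }
    M <<- M + length(S)
  })
  wrong / M
}

# Mean per-symbol negative log-likelihood (nats).
mean_nll <- function(params, seqs) {
  total <- 0
  M <- 0L
  forward_chunked(params, seqs, FALSE, function(tlp, probs, S, idx) {
    total <<- total - sum(tlp)
    M <<- M + length(tlp)
  })
  total / M
}
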