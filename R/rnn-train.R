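# Backpropagation through time for the three unit types, and the SGD
# training loop. Gradients are of the MEAN per-symbol negative
# log-likelihood over the mini-batch, so the learning rate is independent of
# batch size and sequence length.

# Indicator matrix (B x 4) of the previous symbol, for one-hot input algebra.
prev_indicator <- function(prev, B) {
  X <- matrix(0, B, 4L)
  X[cbind(seq_len(B), prev)] <- 1
  X
}

rnn_backward <- function(params, S, fw) {
  spec <- attr(params, "spec")
  H <- spec$hidden
  B <- nrow(S)
  T_ <- ncol(S)
  g <- zero_params(spec)
  type <- spec$unit_type
  scale <- 1 / (B * T_)

  carry_h <- matrix(0, H, B)
  carry_c <- if (type == "lstm") matrix(0, H, B)
  tV <- t(params$V)

  for (t in rev(seq_len(T_))) {
    cc <- fw$cache[[t]]
    dlogits <- cc$p
    dlogits[cbind(S[, t], seq_len(B))] <- dlogits[cbind(S[, t], seq_len(B))] - 1
    g$V <- g$V + dlogits %*% t(cc$h)
    g$c <- g$c + rowSums(dlogits)
    dh <- tV %*% dlogits + carry_h

    prev <- if (t > 1L) S[, t - 1L] else NULL
    Xt <- if (!is.null(prev)) prev_indicator(prev, B)

    if (type == "rnn") {
      da <- dh * (1 - cc$h^2)
      if (!is.null(Xt)) g$W <- g$W + da %*% Xt
      g$U <- g$U + da %*% t(cc$h_prev)
      g$b <- g$b + rowSums(da)
      carry_h <- crossprod(params$U, da)
    } else if (type == "gru") {
      dz <- dh * (cc$h_prev - cc$hc)
      dhc <- dh * (1 - cc$z)
      carry_h <- dh * cc$z
      dah <- dhc * (1 - cc$hc^2)
      if (!is.null(Xt)) g$Wh <- g$Wh + dah %*% Xt
      g$Uh <- g$Uh + dah %*% t(cc$rh)
      rs <- rowSums(dah); g$bh <- g$bh + rs; g$dh <- g$dh + rs
      drh <- crossprod(params$Uh, dah)
      dr <- drh * cc$h_prev
      carry_h <- carry_h + drh * cc$r
      daz <- dz * cc$z * (1 - cc$z)
      dar <- dr * cc$r * (1 - cc$r)
      if (!is.null(Xt)) {
        g$Wz <- g$Wz + daz %*% Xt
        g$Wr <- g$Wr + dar %*% Xt
      }
      g$Uz <- g$Uz + daz %*% t(cc$h_prev)
      g$Ur <- g$Ur + dar %*% t(cc$h_prev)
      rs <- rowSums(daz); g$bz <- g$bz + rs; g$dz <- g$dz + rs
      rs <- rowSums(dar); g$br <- g$br + rs; g$dr <- g$dr + rs
      carry_h <- carry_h + crossprod(params$Uz, daz) + crossprod(params$Ur, dar)
    } else { # lstm
      do_ <- dh * cc$tc
      dct <- carry_c + dh * cc$o * (1 - cc$tc^2)
      df <- dct * cc$c_prev
      di <- dct * cc$g
      dg_ <- dct * cc$i
      carry_c <- dct * cc$f
      dai <- di * cc$i * (1 - cc$i)
      daf <- df * cc$f * (1 - cc$f)
      dao <- do_ * cc$o * (1 - cc$o)
      dag <- dg_ * (1 - cc$g^2)
      if (!is.null(Xt)) {
        g$Wi <- g$Wi + dai %*% Xt
        g$Wf <- g$Wf + daf %*% Xt
        g$Wo <- g$Wo + dao %*% Xt
        g$Wg <- g$Wg + dag %*% Xt
      }
      g$Ui <- g$Ui + dai %*% t(cc$h_prev)
      g$Uf <- g$Uf + daf %*% t(cc$h_prev)
      g$Uo <- g$Uo + dao %*% t(cc$h_prev)
      g$Ug <- g$Ug + dag %*% t(cc$h_prev)
      rs <- rowSums(dai); g$bi <- g$bi + rs; g$di <- g$di + rs
      rs <- rowSums(daf); g$bf <- g$bf + rs; g$df <- g$df + rs
      rs <- rowSums(dao); g$bo <- g$bo + rs; g$do <- g$do + rs
      rs <- rowSums(dag); g$bg <- g$bg + rs; g$dg <- g$dg + rs
      carry_h <- crossprod(params$Ui, dai) + crossprod(params$Uf, daf) +
        crossprod(params$Uo, dao) + crossprod(params$Ug, dag)
    }
  }
  for (nm in names(g)) g[[nm]] <- g[[nm]] * scale
  g
}

# Mean per-symbol NLL of one integer batch (used by the finite-difference
# gradient oracle in the tests as well as by training diagnostics).
batch_loss <- function(params, S) {
  fw <- rnn_forward(params, S)
  -sum(fw$target_lp) / length(fw$target_lp)
}

clip_elementwise <- function(g, clip) {
  if (clip <= 0 || !is.finite(clip)) return(g)
  for (nm in names(g)) g[[nm]] <- pmin(pmax(g[[nm]], -clip), clip)
  g
}

#' Train a nucleotide language model
#'
#' Minimises the mean per-symbol negative log-likelihood of the training
#' sequences by mini-batch gradient descent (RMSprop by default, plain SGD
#' optionally) with backpropagation through time over the full fixed-length
#' sequences. Gradients are clipped element-wise at `config$clip`. After every epoch the validation
#' next-symbol prediction error rate and NLL are recorded; the returned
#' parameters are those of the checkpoint (including the initial one) with
#' the minimum validation error rate, ties broken in favour of the earliest
#' epoch. The whole procedure is reproducible for a given `config$seed`.
#'
#' @param spec An [rnn_spec()].
#' @param dataset A list with character vectors `train`, `validation`,
#'   `test` (a `sequence_dataset` from [split_dataset()] works directly);
#'   `validation` may be empty, in which case the final epoch is selected.
#' @param config A [train_config()].
#' @return An object of class `rnn_model`: list with elements `spec`,
#'   `params` (selected checkpoint), `history` (per-epoch data frame with
#'   train NLL, validation NLL, validation error rate), `selected_epoch`
#'   (0 = initial parameters), and `config`.
#' @export
train_model <- function(spec, dataset, config = train_config()) {
  stopifnot(inherits(spec, "rnn_spec"), inherits(config, "train_config"))
  train <- dataset$train
  val <- dataset$validation
  if (length(train) == 0L) stop_fmt("training set is empty")
  S <- seq_to_int(train)
  Sval <- if (length(val)) seq_to_int(val)
  n <- nrow(S)
  lr <- config$learning_rate

  with_seed(config$seed, {
    params <- init_params(spec, seed = NULL, init_scale = config$init_scale)

    eval_val <- function(p) {
      if (is.null(Sval)) return(c(NA_real_, NA_real_))
      fw <- rnn_forward(p, Sval, keep_probs = TRUE)
      nll <- -sum(fw$target_lp) / length(fw$target_lp)
      wrong <- 0L
      for (t in seq_along(fw$probs)) {
        pred <- max.col(t(fw$probs[[t]]), ties.method = "first")
        wrong <- wrong + sum(pred != Sval[, t])
      }
      c(nll, wrong / length(Sval))
    }

    v0 <- eval_val(params)
    history <- data.frame(epoch = 0L, train_nll = NA_real_,
                          val_nll = v0[1L], val_error = v0[2L])
    best <- list(epoch = 0L, error = v0[2L], params = params)
    rms <- if (config$optimizer == "rmsprop")
      lapply(params, function(m) m * 0)
    rms_decay <- 0.95
    rms_eps <- 1e-8

    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      ep_sym <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1L, n)]
        Sb <- S[idx, , drop = FALSE]
        fw <- rnn_forward(params, Sb, keep_cache = TRUE)
        ep_loss <- ep_loss - sum(fw$target_lp)
        ep_sym <- ep_sym + length(fw$target_lp)
        gr <- clip_elementwise(rnn_backward(params, Sb, fw), config$clip)
        if (is.null(rms)) {
          for (nm in names(params)) params[[nm]] <- params[[nm]] - lr * gr[[nm]]
        } else {
          for (nm in names(params)) {
            rms[[nm]] <- rms_decay * rms[[nm]] + (1 - rms_decay) * gr[[nm]]^2
            params[[nm]] <- params[[nm]] -
              lr * gr[[nm]] / sqrt(rms[[nm]] + rms_eps)
          }
        }
      }
      vv <- eval_val(params)
      history <- rbind(history, data.frame(
        epoch = ep, train_nll = ep_loss / ep_sym,
        val_nll = vv[1L], val_error = vv[2L]))
      if (!is.na(vv[2L]) && vv[2L] < best$error) {
        best <- list(epoch = ep, error = vv[2L], params = params)
      } else if (is.null(Sval)) {
        best <- list(epoch = ep, error = NA_real_, params = params)
      }
    }

    structure(list(spec = spec, params = best$params, history = history,
                   selected_epoch = best$epoch, config = config),
              class = "rnn_model")
  })
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf("%s(4-%d-4) language model: %d parameters, %d epoch(s) trained, checkpoint %d selected\n",
              toupper(x$spec$unit_type), x$spec$hidden,
              count_parameters(x$spec), max(x$history$epoch), x$selected_epoch))
  if (!all(is.na(x$history$val_error))) {
    i <- which(x$history$epoch == x$selected_epoch)
    cat(sprintf("  validation NLL %.4f nats/symbol, error rate %.4f\n",
                x$history$val_nll[i], x$history$val_error[i]))
  }
  invisible(x)
}
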