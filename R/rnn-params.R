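#' Specify a character-level recurrent language model
#'
#' Describes the architecture of a nucleotide language model: the recurrent
#' unit type and the number of hidden units. The alphabet is fixed at the four
#' DNA bases in the order A, C, G, T. Models of this family are written
#' RNN(4-H-4): four input nodes (one-hot base), H hidden units, four output
#' nodes (next-base distribution).
#'
#' @param unit_type One of `"rnn"` (vanilla tanh unit), `"gru"`, `"lstm"`.
#' @param hidden Number of hidden units (positive integer; lightweight models
#'   with `hidden` <= 20 are the intended regime).
#' @return An object of class `rnn_spec`.
#' @examples
#' rnn_spec("gru", 10)
#' @export
rnn_spec <- function(unit_type = c("gru", "lstm", "rnn"), hidden = 10L) {
  unit_type <- match.arg(unit_type)
  hidden <- as.integer(check_scalar_number(hidden, "hidden", lower = 1))
  structure(list(unit_type = unit_type, hidden = hidden, alphabet_size = 4L),
            class = "rnn_spec")
}

#' @export
print.rnn_spec <- function(x, ...) {
  cat(sprintf("%s(4-%d-4) language model spec, %d parameters\n",
              toupper(x$unit_type), x$hidden, count_parameters(x)))
  invisible(x)
}

#' Number of trainable parameters of a model spec
#'
#' Counts every scalar entry of the weight and bias tensors. Gated units
#' (GRU, LSTM) carry both an input-side and a recurrent-side bias vector per
#' gate; the vanilla unit has a single hidden bias. With H hidden units and a
#' 4-letter alphabet:
#' vanilla `4H + H^2 + H + 4H + 4`; GRU `3(4H + H^2 + 2H) + 4H + 4`;
#' LSTM `4(4H + H^2 + 2H) + 4H + 4`. For example GRU with H = 10 has 524
#' parameters and LSTM with H = 20 has 2164.
#'
#' @param spec An [rnn_spec()].
#' @return Integer parameter count.
#' @examples
#' count_parameters(rnn_spec("gru", 10))  # 524
#' @export
count_parameters <- function(spec) {
  stopifnot(inherits(spec, "rnn_spec"))
  H <- spec$hidden
  A <- spec$alphabet_size
  gate <- H * A + H * H + 2L * H        # W, U, input bias, recurrent bias
  out <- A * H + A                      # V, c
  switch(spec$unit_type,
    rnn  = H * A + H * H + H + out,
    gru  = 3L * gate + out,
    lstm = 4L * gate + out)
}

# Names of the parameter tensors for each unit type, with shapes.
param_shapes <- function(spec) {
  H <- spec$hidden
  A <- spec$alphabet_size
  gates <- switch(spec$unit_type,
    rnn = list(W = c(H, A), U = c(H, H), b = c(H, 1L)),
    gru = {
      g <- list()
      for (s in c("z", "r", "h")) {
        g[[paste0("W", s)]] <- c(H, A)
        g[[paste0("U", s)]] <- c(H, H)
        g[[paste0("b", s)]] <- c(H, 1L)
        g[[paste0("d", s)]] <- c(H, 1L)
      }
      g
    },
    lstm = {
      g <- list()
      for (s in c("i", "f", "o", "g")) {
        g[[paste0("W", s)]] <- c(H, A)
        g[[paste0("U", s)]] <- c(H, H)
        g[[paste0("b", s)]] <- c(H, 1L)
        g[[paste0("d", s)]] <- c(H, 1L)
      }
      g
    })
  c(gates, list(V = c(A, H), c = c(A, 1L)))
}

#' Initialise model parameters
#'
#' Weight matrices are drawn i.i.d. uniform on (-`init_scale`, `init_scale`);
#' all bias vectors start at zero. Reproducible for a given `seed`.
#'
#' @param spec An [rnn_spec()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param init_scale Half-width of the uniform initialisation interval.
#' @return An `rnn_params` object: a named list of matrices/column vectors.
#' @export
init_params <- function(spec, seed = NULL, init_scale = 0.08) {
  stopifnot(inherits(spec, "rnn_spec"))
  check_scalar_number(init_scale, "init_scale", lower = 0)
  shapes <- param_shapes(spec)
  bias_names <- grep("^[bdc]", names(shapes), value = TRUE)
  params <- with_seed(seed, {
    lapply(seq_along(shapes), function(i) {
      dm <- shapes[[i]]
      if (names(shapes)[i] %in% bias_names) {
        matrix(0, dm[1L], dm[2L])
      } else {
        matrix(stats::runif(prod(dm), -init_scale, init_scale), dm[1L], dm[2L])
      }
    })
  })
  names(params) <- names(shapes)
  structure(params, class = "rnn_params", spec = spec)
}

# All-zero parameters of the right shapes (also used as a gradient container).
zero_params <- function(spec) {
  shapes <- param_shapes(spec)
  params <- lapply(shapes, function(dm) matrix(0, dm[1L], dm[2L]))
  structure(params, class = "rnn_params", spec = spec)
}

n_param_entries <- function(params) sum(vapply(params, length, integer(1)))

#' Training configuration
#'
#' Mini-batch gradient descent on the mean per-symbol negative
#' log-likelihood, with element-wise gradient clipping. The default
#' optimiser is RMSprop (decay 0.95), whose per-parameter step scaling is
#' needed in practice to pick up the positional structure of context
#' windows; plain SGD is available as `optimizer = "sgd"` (use a larger
#' learning rate, around 0.1, with it).
#'
#' @param epochs Number of passes over the training set (default 30).
#' @param batch_size Mini-batch size.
#' @param learning_rate Step size (default 2e-3, suitable for RMSprop).
#' @param optimizer `"rmsprop"` (default) or `"sgd"`.
#' @param clip Element-wise gradient clip threshold (absolute value).
#' @param seed Integer seed controlling initialisation and batch shuffling.
#' @param init_scale Passed to [init_params()].
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 50L, learning_rate = 2e-3,
                         optimizer = c("rmsprop", "sgd"), clip = 5.0, seed = 1L,
                         init_scale = 0.08) {
  optimizer <- match.arg(optimizer)
  epochs <- as.integer(check_scalar_number(epochs, "epochs", lower = 0))
  batch_size <- as.integer(check_scalar_number(batch_size, "batch_size", lower = 1))
  check_scalar_number(learning_rate, "learning_rate", lower = 1e-12)
  check_scalar_number(clip, "clip", lower = 0)
  check_scalar_number(init_scale, "init_scale", lower = 0)
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, optimizer = optimizer,
                 clip = clip, seed = as.integer(seed),
                 init_scale = init_scale),
            class = "train_config")
}
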