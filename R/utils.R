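# Shared internal helpers: alphabet encoding, seeded RNG scoping, checks.

DNA_ALPHABET <- c("A", "C", "G", "T")

#' @keywords internal
#' @noRd
stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Encode equal-length sequences over {A,C,G,T} as an integer matrix
# (n x T, values 1..4, alphabet order A<C<G<T).
seq_to_int <- function(seqs) {
  if (length(seqs) == 0L) stop_fmt("no sequences supplied")
  L <- nchar(seqs)
  if (length(unique(L)) != 1L)
    stop_fmt("sequences must all have the same length (got lengths %s)",
             paste(unique(L), collapse = ","))
  chars <- strsplit(seqs, "", fixed = TRUE)
  idx <- match(unlist(chars), DNA_ALPHABET)
  if (anyNA(idx)) {
    bad <- unique(unlist(chars)[is.na(idx)])
    stop_fmt("illegal character(s) %s: sequences must be over {A,C,G,T}",
             paste(sQuote(bad), collapse = ", "))
  }
  matrix(idx, nrow = length(seqs), ncol = L[1L], byrow = TRUE)
}

int_to_seq <- function(m) {
  apply(m, 1L, function(r) paste(DNA_ALPHABET[r], collapse = ""))
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. Mersenne-Twister + Inversion, the R defaults, for reproducibility
# across sessions.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  }
  expr
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_fmt("`%s` must be a single finite number in [%s, %s]", name, lower, upper)
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_fmt("`%s` must be TRUE or FALSE", name)
  x
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Column-wise log-softmax with max subtraction; x is a matrix (4 x B).
log_softmax_cols <- function(x) {
  mx <- apply(x, 2L, max)
  sh <- sweep(x, 2L, mx, "-")
  sweep(sh, 2L, log(colSums(exp(sh))), "-")
}
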