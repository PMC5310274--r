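# Per-site bias weights: the ratio of foreground to background model
# sequence probability of the site's context window. Counts are later
# divided by this weight, so contexts enriched among observed read starts
# (weight > 1) are down-weighted.

#' Bias weight of one context sequence
#'
#' `exp(log p_fg(seq) - log p_bg(seq))`, optionally clamped into
#' `[1/clip, clip]` to guard against extreme ratios (off by default).
#'
#' @param fg_model,bg_model Trained `rnn_model` (or `rnn_params`) objects.
#' @param context_seq Context sequence(s) over {A,C,G,T}.
#' @param clip Optional positive clamp bound; `NULL` disables clamping.
#' @return Positive bias weight(s).
#' @export
site_bias <- function(fg_model, bg_model, context_seq, clip = NULL) {
  b <- exp(sequence_log_probs(fg_model, context_seq) -
             sequence_log_probs(bg_model, context_seq))
  if (!is.null(clip)) {
    check_scalar_number(clip, "clip", lower = 1)
    b <- pmin(pmax(b, 1 / clip), clip)
  }
  b
}

#' Build the bias table for a set of counted sites
#'
#' Extracts the `2w+1` context window of every counted exonic read-start
#' site and assigns it the foreground/background probability ratio. Sites
#' whose window is undefined (contig edge or N) receive weight 1.0 (no
#' correction) and are flagged. Deterministic given its inputs.
#'
#' @param fg_model,bg_model Trained `rnn_model` objects.
#' @param genome A [genome()] object.
#' @param counts A `position_counts` object from [count_read_starts()].
#' @param w Window half-width (must match the training windows).
#' @param clip Optional clamp bound passed to [site_bias()].
#' @return A `bias_table`: data frame with columns `contig`, `pos`,
#'   `strand`, `bias`, `flagged`; attribute `w` records the half-width.
#' @export
build_bias_table <- function(fg_model, bg_model, genome, counts, w = 10L,
                             clip = NULL) {
  stopifnot(inherits(counts, "position_counts"))
  sites <- counts$sites
  seqs <- extract_windows(genome, sites, w)
  ok <- !is.na(seqs)
  bias <- rep(1.0, nrow(sites))
  if (any(ok)) bias[ok] <- site_bias(fg_model, bg_model, seqs[ok], clip = clip)
  out <- data.frame(contig = sites$contig, pos = sites$pos,
                    strand = sites$strand, bias = bias, flagged = !ok)
  attr(out, "w") <- as.integer(w)
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Write / read a bias table TSV
#'
#' Columns: contig, pos (0-based), strand, bias, flagged.
#'
#' @param table A `bias_table`.
#' @param path File path.
#' @export
write_bias_table <- function(table, path) {
  df <- as.data.frame(table)
  df$bias <- sprintf("%.17g", df$bias)
  df$flagged <- as.integer(df$flagged)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path) {
  if (!file.exists(path)) stop_fmt("bias table not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "character",
                                         "numeric", "integer"))
  df$flagged <- as.logical(df$flagged)
  if (any(!is.finite(df$bias)) || any(df$bias <= 0))
    stop_fmt("bias weights must be positive and finite")
  class(df) <- c("bias_table", "data.frame")
  df
}
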