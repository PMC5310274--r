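# Shared fixtures and independent oracles for the test suite.
# All fixtures are built in code; nothing is read from disk except files the
# tests themselves write to tempdir().

BASES <- c("A", "C", "G", "T")

# All 4^L sequences of length L (brute-force enumeration oracle).
enum_seqs <- function(L) {
  grid <- expand.grid(rep(list(BASES), L), stringsAsFactors = FALSE)
  apply(grid, 1L, paste, collapse = "")
}

rand_seqs <- function(n, L, seed) {
  set.seed(seed)
  apply(matrix(sample(BASES, n * L, replace = TRUE), n, L), 1L,
        paste, collapse = "")
}

# Sequences from a first-order Markov chain with transition matrix P
# (rows = current base, columns = next base), uniform initial distribution.
markov_seqs <- function(n, L, P, seed) {
  set.seed(seed)
  S <- matrix(0L, n, L)
  S[, 1L] <- sample.int(4L, n, replace = TRUE)
  cum <- t(apply(P, 1L, cumsum))
  for (t in 2:L) {
    r <- stats::runif(n)
    S[, t] <- max.col(cum[S[, t - 1L], , drop = FALSE] >= r, ties.method = "first")
  }
  apply(S, 1L, function(x) paste(BASES[x], collapse = ""))
}

# The Markov generator used for language-model recovery checks: each base
# strongly favours its alphabet successor (A->C, C->G, G->T, T->A).
markov_P <- function(p_hot = 0.55) {
  P <- matrix((1 - p_hot) / 3, 4L, 4L)
  for (a in 1:4) P[a, (a %% 4L) + 1L] <- p_hot
  P
}

# Central finite-difference gradient of the mean per-symbol NLL, the
# independent oracle for the analytic BPTT gradients.
numeric_gradient <- function(params, S, eps = 1e-5) {
  g <- lapply(params, function(m) m * 0)
  for (nm in names(params)) {
    for (i in seq_along(params[[nm]])) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      g[[nm]][i] <- (rnnbias:::batch_loss(pp, S) -
                       rnnbias:::batch_loss(pm, S)) / (2 * eps)
    }
  }
  g
}

max_rel_grad_err <- function(analytic, numeric) {
  max(unlist(Map(function(a, b) abs(a - b) / pmax(1e-8, abs(a) + abs(b)),
                 analytic, numeric[names(analytic)])))
}

# Mean KL divergence between generator transition rows and the model's
# average predictive distribution conditioned on the previous symbol.
markov_mean_kl <- function(model, seqs, P) {
  pp <- predictive_probs(model, seqs)
  S <- rnnbias:::seq_to_int(seqs)
  L <- ncol(S)
  kl <- 0
  for (a in 1:4) {
    sel <- which(S[, seq_len(L - 1L), drop = FALSE] == a, arr.ind = TRUE)
    q <- vapply(1:4, function(b) mean(pp[cbind(sel[, 1L], sel[, 2L] + 1L, b)]),
                0)
    kl <- kl + sum(P[a, ] * log(P[a, ] / q))
  }
  kl / 4
}

# A tiny deterministic genome fixture with a known sequence.
tiny_genome <- function() genome(c(c1 = "AACCGGTTAACCGGTTAACCGGTT",
                                   c2 = "ACGTACGTACGTACGTACGTACGTACGT"))

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# One BED12 line; blocks given as (relative start, size) pairs.
bed12_line <- function(contig = "c1", chrom_start = 100L, name = "g1",
                       strand = "+", sizes = c(50L, 30L),
                       starts = c(0L, 100L)) {
  chrom_end <- chrom_start + starts[length(starts)] + sizes[length(sizes)]
  paste(contig, chrom_start, chrom_end, name, 0L, strand, chrom_start,
        chrom_end, "0", length(sizes),
        paste0(paste(sizes, collapse = ","), ","),
        paste0(paste(starts, collapse = ","), ","), sep = "\t")
}

sam_header <- function(contigs = c(c1 = 2000L)) {
  c("@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs))
}

sam_record <- function(qname = "r1", flag = 0L, contig = "c1", pos1 = 1000L,
                       mapq = 255L, cigar = "100M", tags = character()) {
  paste(c(qname, flag, contig, pos1, mapq, cigar, "*", 0L, 0L, "*", "*", tags),
        collapse = "\t")
}

# The scaled-down end-to-end pipeline used for recovery checks: simulator
# defaults, 3000 foreground/background windows, GRU-10 trained by rmsprop
# (lr 3e-3, 12 epochs). Returns per-run metrics.
run_recovery_pipeline <- function(seed, pwm, n_seq = 3000L, epochs = 12L,
                                  lr = 3e-3, unit = "gru", hidden = 10L) {
  sim <- simulate_dataset(sim_config(pwm = pwm, seed = seed))
  counts <- count_read_starts(sim$sites, sim$gene_models)
  fg <- sample_foreground_sites(counts, n_seq, seed = seed + 1000L)
  bg <- sample_background_sites(fg, max_offset = 30L, genome = sim$genome,
                                seed = seed + 2000L, w = 10L)
  fg_seqs <- extract_context_sequences(fg, sim$genome, 10L, "foreground")
  bg_seqs <- extract_context_sequences(bg, sim$genome, 10L, "background")
  fds <- split_dataset(fg_seqs$seq, seed = seed + 3000L)
  bds <- split_dataset(bg_seqs$seq, seed = seed + 4000L)
  fgm <- train_model(rnn_spec(unit, hidden), fds,
                     train_config(epochs = epochs, learning_rate = lr,
                                  seed = seed + 5000L))
  bgm <- train_model(rnn_spec(unit, hidden), bds,
                     train_config(epochs = epochs, learning_rate = lr,
                                  seed = seed + 6000L))
  bt <- build_bias_table(fgm, bgm, sim$genome, counts, w = 10L)
  et <- quantify(counts, sim$gene_models, bt)
  truth <- sim$truth$genes$abundance
  shift <- expression_shift(et$raw_fpkm, et$corrected_fpkm)
  list(spearman_raw = stats::cor(et$raw_fpkm, truth, method = "spearman"),
       spearman_corrected = stats::cor(et$corrected_fpkm, truth,
                                       method = "spearman"),
       log_rms_shift = shift$euclidean,
       geo_mean_bias = exp(mean(log(bt$bias))),
       fg_model = fgm, bg_model = bgm,
       fg_test = fds$test, bg_test = bds$test,
       expression = et)
}
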