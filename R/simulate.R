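# Synthetic-data generator: a random genome, non-overlapping gene models,
# log-normal ground-truth abundances, and read starts drawn with a KNOWN
# injected sequence-specific bias. The bias ground truth is a log-linear
# positional weight matrix (PWM) over the context window, the mechanism this
# class of correction method is designed to capture, and the simplest one
# that admits closed-form checks.

#' Simulation configuration
#'
#' @param contig_length Length of the single simulated contig (bp).
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per gene.
#' @param exon_length Length of each exon (bp).
#' @param intron_range Min/max intron length (sampled uniformly).
#' @param gap_range Min/max intergenic gap (sampled uniformly).
#' @param meanlog,sdlog Log-normal law for ground-truth gene abundances
#'   (normalised to sum to 1).
#' @param n_reads Total number of simulated reads.
#' @param pwm Bias PWM: a `(2w+1) x 4` matrix of log-weights (columns
#'   A,C,G,T), or `NULL` for no injected bias.
#' @param w Context-window half-width.
#' @param read_length Read length used by the optional SAM output.
#' @param contig_name Name of the simulated contig.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(contig_length = 200000L, n_genes = 100L,
                       exons_per_gene = 3L, exon_length = 150L,
                       intron_range = c(60L, 200L), gap_range = c(100L, 400L),
                       meanlog = 0, sdlog = 1, n_reads = 50000L,
                       pwm = NULL, w = 10L, read_length = 50L,
                       contig_name = "sim1", seed = 1L) {
  w <- as.integer(check_scalar_number(w, "w", lower = 1))
  if (!is.null(pwm)) {
    pwm <- as.matrix(pwm)
    if (nrow(pwm) != 2L * w + 1L || ncol(pwm) != 4L || any(!is.finite(pwm)))
      stop_fmt("`pwm` must be a finite (2w+1) x 4 matrix (%d x 4)", 2L * w + 1L)
  }
  cfg <- list(contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length = as.integer(exon_length),
              intron_range = as.integer(intron_range),
              gap_range = as.integer(gap_range),
              meanlog = meanlog, sdlog = sdlog,
              n_reads = as.integer(n_reads), pwm = pwm, w = w,
              read_length = as.integer(read_length),
              contig_name = contig_name, seed = as.integer(seed))
  for (nm in c("contig_length", "n_genes", "exons_per_gene", "exon_length",
               "n_reads", "read_length"))
    check_scalar_number(cfg[[nm]], nm, lower = 1)
  structure(cfg, class = "sim_config")
}

#' PWM weight of a context sequence
#'
#' `exp(sum_j M[j, seq_j])`: the injected selection weight of a read start
#' whose context window is `seq`.
#'
#' @param M `(2w+1) x 4` matrix of log-weights, columns in order A,C,G,T.
#' @param seq Character vector of sequences of length `2w+1` over {A,C,G,T}.
#' @return Positive weight(s).
#' @export
pwm_weight <- function(M, seq) {
  M <- as.matrix(M)
  S <- seq_to_int(seq)
  if (ncol(S) != nrow(M))
    stop_fmt("sequence length %d does not match PWM rows %d", ncol(S), nrow(M))
  lw <- numeric(nrow(S))
  for (j in seq_len(nrow(M))) lw <- lw + M[j, S[, j]]
  exp(lw)
}

#' A strong example bias PWM
#'
#' Places one favoured (+`strength`) and one disfavoured (-`strength`) base
#' at each of the five positions centred on the read start; the remaining
#' positions are neutral. With the default strength `log(3)` this injects a
#' pronounced context-dependent selection bias.
#'
#' @param w Window half-width.
#' @param strength Log-weight magnitude.
#' @return `(2w+1) x 4` matrix of log-weights.
#' @export
example_bias_pwm <- function(w = 10L, strength = log(3)) {
  M <- matrix(0, 2L * w + 1L, 4L, dimnames = list(NULL, DNA_ALPHABET))
  for (k in -2:2) {
    row <- w + 1L + k
    M[row, ((k + 2L) %% 4L) + 1L] <- strength
    M[row, ((k + 3L) %% 4L) + 1L] <- -strength
  }
  M
}

# Lay out non-overlapping genes left to right; errors if they do not fit.
place_genes <- function(cfg) {
  margin <- cfg$w + 1L
  cursor <- margin
  genes <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    gap <- sample(cfg$gap_range[1L]:cfg$gap_range[2L], 1L)
    introns <- if (cfg$exons_per_gene > 1L)
      sample(cfg$intron_range[1L]:cfg$intron_range[2L],
             cfg$exons_per_gene - 1L, replace = TRUE) else integer()
    start <- cursor + gap
    ex_start <- start + c(0L, cumsum(cfg$exon_length + introns))
    ex_end <- ex_start + cfg$exon_length
    genes[[i]] <- structure(
      list(gene_id = sprintf("gene%03d", i), contig = cfg$contig_name,
           strand = "+", exons = cbind(start = ex_start, end = ex_end)),
      class = "gene_model")
    cursor <- ex_end[length(ex_end)]
  }
  if (cursor + margin > cfg$contig_length)
    stop_fmt("genes unplaceable: need %d bp but contig_length is %d",
             cursor + margin, cfg$contig_length)
  genes
}

#' Simulate a biased RNA-seq read-start dataset
#'
#' Generates an i.i.d.-uniform random genome, places non-overlapping
#' forward-strand genes with at least `w` bp of margin from the contig ends,
#' draws normalised log-normal gene abundances, and samples `n_reads` read
#' 5'-end positions from a single categorical distribution over all exonic
#' positions with weight `abundance(gene) x pwm_weight(context window)` —
#' i.e. a read's selection probability depends jointly on how abundant its
#' transcript is and on the nucleotide context around the priming site,
#' which is exactly the coupling the correction pipeline is meant to undo.
#' With a zero (or `NULL`) PWM, positions within a gene are uniform and
#' per-gene totals are proportional to abundance times exonic length, so
#' FPKM estimates abundance.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, writes `genome.fa`,
#'   `genes.bed` (BED12), `reads.tsv` (read-start TSV), `truth_genes.tsv`,
#'   `truth_sites.tsv` and `config.json` (and `reads.sam` if `sam = TRUE`).
#' @param sam Also write a minimal SAM file (one record per read, forward
#'   strand, fixed-length reads), for exercising the SAM input path.
#' @return List with `genome`, `gene_models`, `sites` (read-start data
#'   frame), `truth` (list with per-gene `abundance` data frame and
#'   per-site `weights` data frame), and `paths` (when `out_dir` given).
#' @export
simulate_dataset <- function(config, out_dir = NULL, sam = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    gen <- genome(stats::setNames(
      paste(sample(DNA_ALPHABET, config$contig_length, replace = TRUE),
            collapse = ""),
      config$contig_name))
    gene_models <- place_genes(config)
    ab <- stats::rlnorm(config$n_genes, config$meanlog, config$sdlog)
    ab <- ab / sum(ab)

    pos_list <- lapply(gene_models, function(g) {
      unlist(lapply(seq_len(nrow(g$exons)),
                    function(j) g$exons[j, "start"]:(g$exons[j, "end"] - 1L)))
    })
    pos <- unlist(pos_list)
    gene_of <- rep(seq_along(gene_models), lengths(pos_list))
    windows <- extract_windows(gen, data.frame(contig = config$contig_name,
                                               pos = pos, strand = "+"),
                               config$w)
    stopifnot(!anyNA(windows))  # margin placement guarantees validity
    vw <- if (is.null(config$pwm)) rep(1, length(pos))
          else pwm_weight(config$pwm, windows)
    prob <- ab[gene_of] * vw
    counts <- as.integer(stats::rmultinom(1L, config$n_reads, prob))

    keep <- counts > 0L
    sites <- data.frame(contig = config$contig_name, pos = pos[keep],
                        strand = "+", count = counts[keep])
    class(sites) <- c("read_starts", "data.frame")
    truth <- list(
      genes = data.frame(gene_id = vapply(gene_models, `[[`, "", "gene_id"),
                         abundance = ab,
                         length = vapply(gene_models, gene_length, 0L)),
      weights = data.frame(contig = config$contig_name, pos = pos[keep],
                           strand = "+", weight = vw[keep]))

    paths <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        genome = file.path(out_dir, "genome.fa"),
        genes = file.path(out_dir, "genes.bed"),
        reads = file.path(out_dir, "reads.tsv"),
        truth_genes = file.path(out_dir, "truth_genes.tsv"),
        truth_sites = file.path(out_dir, "truth_sites.tsv"),
        config = file.path(out_dir, "config.json"))
      write_fasta(gen, paths$genome)
      write_bed12(gene_models, paths$genes)
      write_read_starts(sites, paths$reads)
      df <- truth$genes
      df$abundance <- sprintf("%.17g", df$abundance)
      utils::write.table(df, paths$truth_genes, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      dfw <- truth$weights
      dfw$weight <- sprintf("%.17g", dfw$weight)
      utils::write.table(dfw, paths$truth_sites, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      cfg <- unclass(config)
      cfg$pwm <- if (is.null(cfg$pwm)) NULL else unname(apply(cfg$pwm, 1L, c, simplify = FALSE))
      jsonlite::write_json(cfg, paths$config, digits = I(17), auto_unbox = TRUE,
                           null = "null")
      if (sam) {
        paths$sam <- file.path(out_dir, "reads.sam")
        write_sim_sam(gen, sites, config$read_length, paths$sam)
      }
    }
    list(genome = gen, gene_models = gene_models, sites = sites,
         truth = truth, paths = paths)
  })
}

#' Write gene models as BED12
#' @param gene_models List of `gene_model` objects.
#' @param path Output path.
#' @export
write_bed12 <- function(gene_models, path) {
  lines <- vapply(gene_models, function(g) {
    s <- g$exons[, "start"]; e <- g$exons[, "end"]
    cs <- s[1L]; ce <- e[length(e)]
    paste(g$contig, cs, ce, g$gene_id, 0L, g$strand, cs, ce, "0",
          nrow(g$exons), paste0(paste(e - s, collapse = ","), ","),
          paste0(paste(s - cs, collapse = ","), ","), sep = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Minimal SAM writer: one primary forward-strand record per simulated read.
write_sim_sam <- function(gen, sites, read_length, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               paste0("@SQ\tSN:", names(gen), "\tLN:", nchar(gen))), con)
  clen <- nchar(gen)[sites$contig]
  rl <- pmin(read_length, clen - sites$pos)
  idx <- rep(seq_len(nrow(sites)), sites$count)
  qname <- sprintf("simread%06d", seq_along(idx))
  seqs <- substr(unclass(gen)[sites$contig[idx]], sites$pos[idx] + 1L,
                 sites$pos[idx] + rl[idx])
  writeLines(paste(qname, 0L, sites$contig[idx], sites$pos[idx] + 1L, 255L,
                   paste0(rl[idx], "M"), "*", 0L, 0L, seqs, "*", "NH:i:1",
                   sep = "\t"), con)
  invisible(path)
}
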