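# Exonic read-start counting, foreground/background site sampling, context
# sequence extraction and train/validation/test splitting.

exon_granges <- function(gene_models) {
  gid <- rep(vapply(gene_models, `[[`, "", "gene_id"),
             vapply(gene_models, function(g) nrow(g$exons), 0L))
  starts <- unlist(lapply(gene_models, function(g) g$exons[, "start"]))
  ends <- unlist(lapply(gene_models, function(g) g$exons[, "end"]))
  contig <- rep(vapply(gene_models, `[[`, "", "contig"),
                vapply(gene_models, function(g) nrow(g$exons), 0L))
  GenomicRanges::GRanges(contig,
                         IRanges::IRanges(start = starts + 1L, end = ends),
                         gene_id = gid)
}

sites_granges <- function(sites) {
  GenomicRanges::GRanges(sites$contig,
                         IRanges::IRanges(start = sites$pos + 1L, width = 1L))
}

#' Restrict read-start sites to annotated exons
#'
#' Keeps the sites whose position falls inside any exon of any gene
#' (0-based half-open intervals: a site at `end - 1` is inside, one at `end`
#' is not) and records the total number of retained reads, the denominator
#' used later by FPKM.
#'
#' @param sites A `read_starts` data frame from [read_read_starts()].
#' @param gene_models List of `gene_model` objects.
#' @return A `position_counts` object: list with `sites` (aggregated
#'   exonic read-start data frame) and `total_mapped`.
#' @export
count_read_starts <- function(sites, gene_models) {
  if (nrow(sites)) {
    hits <- GenomicRanges::findOverlaps(sites_granges(sites),
                                        exon_granges(gene_models),
                                        ignore.strand = TRUE)
    keep <- sort(unique(S4Vectors::queryHits(hits)))
    sites <- sites[keep, , drop = FALSE]
  }
  sites <- aggregate_sites(sites)
  class(sites) <- c("read_starts", "data.frame")
  structure(list(sites = sites, total_mapped = sum(sites$count)),
            class = "position_counts")
}

#' @export
print.position_counts <- function(x, ...) {
  cat(sprintf("%d exonic read-start site(s), %d mapped reads\n",
              nrow(x$sites), x$total_mapped))
  invisible(x)
}

#' Sample foreground sites
#'
#' Draws `n` sites with replacement with probability proportional to read
#' count, i.e. uniformly over the read multiset, so frequently used start
#' positions dominate the foreground training sample.
#'
#' @param counts A `position_counts` object.
#' @param n Number of sites to draw (>= 1).
#' @param seed Integer seed.
#' @param weight_by_count Sample reads (`TRUE`, default) or positions
#'   (`FALSE`, each distinct site equally likely).
#' @return Data frame with columns `contig`, `pos`, `strand`, one row per
#'   sampled site.
#' @export
sample_foreground_sites <- function(counts, n, seed = NULL,
                                    weight_by_count = TRUE) {
  stopifnot(inherits(counts, "position_counts"))
  n <- as.integer(check_scalar_number(n, "n", lower = 1))
  if (nrow(counts$sites) == 0L) stop_fmt("no exonic read-start sites to sample")
  prob <- if (weight_by_count) counts$sites$count else NULL
  idx <- with_seed(seed,
                   sample.int(nrow(counts$sites), n, replace = TRUE, prob = prob))
  out <- counts$sites[idx, c("contig", "pos", "strand")]
  rownames(out) <- NULL
  out
}

#' Sample background sites by random offsets
#'
#' For each foreground site, draws an offset uniformly from
#' `{-max_offset..-1, 1..max_offset}` (never 0) and shifts the position,
#' keeping contig and strand. If the shifted window of half-width `w` would
#' leave the contig, the offset is redrawn up to `retries` times; sites with
#' no valid offset are dropped with a warning.
#'
#' @param fg_sites Data frame of foreground sites (`contig`, `pos`, `strand`).
#' @param max_offset Maximum absolute offset (default 30, keeping background
#'   sequences in the same genomic neighbourhood).
#' @param genome A [genome()] object (for bounds checking).
#' @param seed Integer seed.
#' @param w Window half-width used for the validity check.
#' @param retries Redraw attempts per site.
#' @return Data frame of background sites, same columns as `fg_sites`.
#' @export
sample_background_sites <- function(fg_sites, max_offset = 30L, genome = NULL,
                                    seed = NULL, w = 10L, retries = 20L) {
  max_offset <- as.integer(check_scalar_number(max_offset, "max_offset", lower = 1))
  w <- as.integer(check_scalar_number(w, "w", lower = 0))
  n <- nrow(fg_sites)
  clen <- if (!is.null(genome)) nchar(genome)[fg_sites$contig] else rep(Inf, n)
  support <- c(-(max_offset:1), 1:max_offset)
  pos <- with_seed(seed, {
    p <- fg_sites$pos + sample(support, n, replace = TRUE)
    bad <- which(p - w < 0L | p + w > clen - 1L)
    tries <- 0L
    while (length(bad) && tries < retries) {
      p[bad] <- fg_sites$pos[bad] + sample(support, length(bad), replace = TRUE)
      bad <- bad[p[bad] - w < 0L | p[bad] + w > clen[bad] - 1L]
      tries <- tries + 1L
    }
    p[bad] <- NA_integer_
    p
  })
  keep <- !is.na(pos)
  if (any(!keep))
    warning(sprintf("%d background site(s) had no valid offset after %d retries and were dropped",
                    sum(!keep), retries), call. = FALSE)
  out <- data.frame(contig = fg_sites$contig[keep], pos = pos[keep],
                    strand = fg_sites$strand[keep])
  rownames(out) <- NULL
  out
}

#' Extract context sequences for a set of sites
#'
#' Applies [extract_windows()] and drops sites whose window is invalid
#' (contig boundary or N), the boundary filter that removes sequences
#' shorter than the full `2w+1` window.
#'
#' @param sites Data frame with `contig`, `pos`, `strand`.
#' @param genome A [genome()] object.
#' @param w Half-width (default 10, i.e. 21-bp windows; 20 gives the 41-bp
#'   extended mode).
#' @param origin `"foreground"` or `"background"` tag.
#' @return Data frame with columns `seq`, `origin`, `contig`, `pos`,
#'   `strand`; every `seq` has length exactly `2w+1`.
#' @export
extract_context_sequences <- function(sites, genome, w = 10L,
                                      origin = c("foreground", "background")) {
  origin <- match.arg(origin)
  seqs <- extract_windows(genome, sites, w)
  keep <- !is.na(seqs)
  out <- data.frame(seq = seqs[keep], origin = origin,
                    contig = sites$contig[keep], pos = sites$pos[keep],
                    strand = sites$strand[keep])
  rownames(out) <- NULL
  out
}

#' Shuffle-and-split sequences into train/validation/test
#'
#' Random shuffle under `seed`, then a contiguous split: the train size is
#' `round(p1 * n)`, validation `round(p2 * n)`, and the remainder goes to
#' the test set.
#'
#' @param seqs Character vector of sequences.
#' @param proportions Numeric triple summing to 1 (default 90:5:5).
#' @param seed Integer seed.
#' @return A `sequence_dataset`: list with `train`, `validation`, `test`
#'   and `proportions`.
#' @export
split_dataset <- function(seqs, proportions = c(0.9, 0.05, 0.05), seed = NULL) {
  if (length(proportions) != 3L || any(proportions <= 0) ||
      abs(sum(proportions) - 1) > 1e-9)
    stop_fmt("`proportions` must be three positive numbers summing to 1")
  n <- length(seqs)
  ord <- with_seed(seed, sample.int(n))
  n_train <- round(proportions[1L] * n)
  n_val <- round(proportions[2L] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  shuffled <- seqs[ord]
  structure(list(train = shuffled[seq_len(n_train)],
                 validation = if (n_val > 0) shuffled[n_train + seq_len(n_val)] else character(),
                 test = if (n - n_train - n_val > 0) shuffled[(n_train + n_val + 1L):n] else character(),
                 proportions = proportions),
            class = "sequence_dataset")
}

#' @export
print.sequence_dataset <- function(x, ...) {
  cat(sprintf("sequence dataset: %d train / %d validation / %d test\n",
              length(x$train), length(x$validation), length(x$test)))
  invisible(x)
}

#' Write / read plain-text sequence files (one sequence per line)
#' @param seqs Character vector.
#' @param path File path.
#' @export
write_sequences <- function(seqs, path) {
  writeLines(seqs, path)
  invisible(path)
}

#' @rdname write_sequences
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop_fmt("sequence file not found: %s", path)
  readLines(path)
}
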