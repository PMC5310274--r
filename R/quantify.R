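# Gene-level FPKM with and without bias reweighting, evaluation metrics and
# before/after shift diagnostics.

#' Gene expression as (bias-corrected) FPKM
#'
#' Raw expression of a gene is
#' `1e9 * sum_i count_i / (length(gene) * total_mapped)`, the usual
#' reads-per-kilobase-per-million normalisation over the gene's exonic
#' read-start positions. When a bias table is supplied, the numerator uses
#' `sum_i count_i / bias_i` while the denominator keeps the raw total mapped
#' read count. Positions falling in the exons of several genes contribute to
#' each of them.
#'
#' @param counts A `position_counts` from [count_read_starts()].
#' @param gene_models List of `gene_model` objects.
#' @param bias_table Optional `bias_table` from [build_bias_table()].
#' @return An `expression_table` data frame: `gene_id`, `length`,
#'   `raw_count`, `effective_count`, `raw_fpkm` and (if a bias table was
#'   given) `corrected_fpkm`.
#' @export
quantify <- function(counts, gene_models, bias_table = NULL) {
  stopifnot(inherits(counts, "position_counts"))
  total <- counts$total_mapped
  if (total <= 0) stop_fmt("total mapped read count is zero")
  sites <- counts$sites
  gid <- vapply(gene_models, `[[`, "", "gene_id")
  glen <- vapply(gene_models, gene_length, 0L)
  if (any(glen <= 0)) stop_fmt("gene(s) with non-positive exonic length")

  eff <- sites$count
  if (!is.null(bias_table)) {
    key_s <- paste(sites$contig, sites$pos, sites$strand, sep = "\r")
    key_b <- paste(bias_table$contig, bias_table$pos, bias_table$strand, sep = "\r")
    m <- match(key_s, key_b)
    b <- ifelse(is.na(m), 1.0, bias_table$bias[m])
    eff <- sites$count / b
  }

  raw_count <- numeric(length(gid))
  eff_count <- numeric(length(gid))
  if (nrow(sites)) {
    ex <- exon_granges(gene_models)
    hits <- GenomicRanges::findOverlaps(sites_granges(sites), ex,
                                        ignore.strand = TRUE)
    qi <- S4Vectors::queryHits(hits)
    gi <- match(ex$gene_id[S4Vectors::subjectHits(hits)], gid)
    # a site may hit several exons of the same gene only if exons overlap,
    # which gene models forbid; several genes are allowed
    raw_count <- raw_count + as.numeric(tapply(sites$count[qi], factor(gi, levels = seq_along(gid)), sum, default = 0))
    eff_count <- eff_count + as.numeric(tapply(eff[qi], factor(gi, levels = seq_along(gid)), sum, default = 0))
  }
  out <- data.frame(gene_id = gid, length = glen,
                    raw_count = raw_count, effective_count = eff_count,
                    raw_fpkm = 1e9 * raw_count / (glen * total))
  if (!is.null(bias_table))
    out$corrected_fpkm <- 1e9 * eff_count / (glen * total)
  class(out) <- c("expression_table", "data.frame")
  attr(out, "total_mapped") <- total
  out
}

#' Write an expression table TSV
#' @param table An `expression_table`.
#' @param path File path.
#' @export
write_expression_table <- function(table, path) {
  df <- as.data.frame(table)
  for (col in intersect(c("effective_count", "raw_fpkm", "corrected_fpkm"),
                        names(df)))
    df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation between predicted and reference expression
#'
#' Pairs where either value is non-positive are dropped (mirroring
#' evaluation against non-zero RT-PCR measurements); the log-adjusted
#' Pearson correlation is computed on log10 of both sides, the Spearman
#' correlation on the (filtered) raw values, and r² is the square of the
#' log-Pearson correlation.
#'
#' @param pred,ref Paired non-negative expression vectors.
#' @return List with `pearson_log`, `spearman`, `r2`, `n` (pairs surviving
#'   the positivity filter).
#' @export
correlation_metrics <- function(pred, ref) {
  if (length(pred) != length(ref)) stop_fmt("`pred` and `ref` lengths differ")
  keep <- is.finite(pred) & is.finite(ref) & pred > 0 & ref > 0
  if (sum(keep) < 3L)
    stop_fmt("fewer than 3 positive pairs survive filtering (%d)", sum(keep))
  p <- pred[keep]; r <- ref[keep]
  pearson_log <- stats::cor(log10(p), log10(r))
  list(pearson_log = pearson_log,
       spearman = stats::cor(p, r, method = "spearman"),
       r2 = pearson_log^2,
       n = sum(keep))
}

#' Expression shift diagnostics before vs after correction
#'
#' Per-gene log-fold change `log10((corrected + eps) / (raw + eps))`; the
#' Euclidean distance is reported as the root-mean-square log-fold change so
#' that it does not scale with the number of genes, and genes are counted as
#' increased (log-fold > 0) or decreased (< 0).
#'
#' @param raw_table,corrected_table `expression_table`s over the same genes
#'   (the corrected one must carry `corrected_fpkm`); alternatively two
#'   numeric vectors of FPKM values.
#' @param epsilon Pseudocount guarding zero expression.
#' @return List with `euclidean`, `n_increased`, `n_decreased`, `logfold`.
#' @export
expression_shift <- function(raw_table, corrected_table, epsilon = 1e-6) {
  if (is.data.frame(raw_table)) {
    if (is.data.frame(corrected_table)) {
      if (!identical(raw_table$gene_id, corrected_table$gene_id))
        stop_fmt("gene sets of the two tables differ")
      raw <- raw_table$raw_fpkm
      corrected <- corrected_table$corrected_fpkm
      if (is.null(corrected)) stop_fmt("corrected table has no corrected_fpkm")
    } else stop_fmt("both arguments must be tables or both vectors")
  } else {
    raw <- raw_table
    corrected <- corrected_table
    if (length(raw) != length(corrected)) stop_fmt("gene sets differ in size")
  }
  check_scalar_number(epsilon, "epsilon", lower = 0)
  logfold <- log10((corrected + epsilon) / (raw + epsilon))
  list(euclidean = sqrt(mean(logfold^2)),
       n_increased = sum(logfold > 0),
       n_decreased = sum(logfold < 0),
       logfold = logfold)
}
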