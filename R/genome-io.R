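# Readers for the genomic formats the pipeline consumes (FASTA, BED12, SAM,
# read-start TSV) and strand-aware context-window extraction.
#
# Coordinate conventions: 0-based half-open internally everywhere. SAM input
# (1-based) is converted on read; BED is natively 0-based half-open.

#' Construct a genome object
#'
#' @param contigs Named character vector of nucleotide sequences over
#'   {A,C,G,T,N} (lowercase accepted, stored uppercase).
#' @return An object of class `genome`: a named uppercase character vector.
#' @export
genome <- function(contigs) {
  if (length(contigs) == 0L) stop_fmt("a genome needs at least one contig")
  nms <- names(contigs)
  if (is.null(nms) || any(!nzchar(nms))) stop_fmt("every contig must be named")
  if (anyDuplicated(nms))
    stop_fmt("duplicate contig name(s): %s",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
  contigs <- toupper(contigs)
  if (any(!nzchar(contigs))) stop_fmt("contigs must be non-empty")
  bad <- grepl("[^ACGTN]", contigs)
  if (any(bad))
    stop_fmt("contig %s contains characters outside {A,C,G,T,N}",
             nms[which(bad)[1L]])
  structure(contigs, class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("genome with %d contig(s), %d bp total\n",
              length(x), sum(nchar(x))))
  invisible(x)
}

#' Read a reference genome from FASTA
#'
#' Multi-line records are concatenated; lowercase is folded to uppercase.
#' Only {A,C,G,T,N} are legal.
#'
#' @param path FASTA file path.
#' @return A [genome()] object; contig order follows the file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_fmt("FASTA file not found: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop_fmt("malformed FASTA in %s: %s",
                                               path, conditionMessage(e)))
  if (length(set) == 0L) stop_fmt("no FASTA records in %s", path)
  seqs <- as.character(set)
  # header up to first whitespace, the usual contig-name convention
  names(seqs) <- sub("\\s.*$", "", names(set))
  genome(seqs)
}

#' Write a genome to FASTA
#'
#' @param genome A [genome()] object.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from BED12
#'
#' Exon intervals are reconstructed from the block columns in 0-based
#' half-open genome coordinates. Lines whose blockCount disagrees with the
#' blockSizes/blockStarts lists, or whose blocks are unsorted or overlapping,
#' are format errors.
#'
#' @param path BED12 file path.
#' @return List of `gene_model` objects, each a list with `gene_id`,
#'   `contig`, `strand` and `exons` (two-column matrix of 0-based half-open
#'   start/end).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop_fmt("BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track") & !startsWith(lines, "browser")]
  if (length(lines) == 0L) stop_fmt("no records in %s", path)
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L)
      stop_fmt("%s line %d: BED12 requires 12 fields, found %d", path, i, length(f))
    chrom_start <- suppressWarnings(as.integer(f[2L]))
    chrom_end <- suppressWarnings(as.integer(f[3L]))
    strand <- f[6L]
    n_blocks <- suppressWarnings(as.integer(f[10L]))
    sizes <- suppressWarnings(as.integer(strsplit(sub(",$", "", f[11L]), ",")[[1L]]))
    starts <- suppressWarnings(as.integer(strsplit(sub(",$", "", f[12L]), ",")[[1L]]))
    if (is.na(chrom_start) || is.na(chrom_end) || is.na(n_blocks) ||
        anyNA(sizes) || anyNA(starts))
      stop_fmt("%s line %d: non-numeric BED12 coordinate field", path, i)
    if (!strand %in% c("+", "-"))
      stop_fmt("%s line %d: strand must be + or -, found %s", path, i, sQuote(strand))
    if (length(sizes) != n_blocks || length(starts) != n_blocks)
      stop_fmt("%s line %d: blockCount %d disagrees with %d sizes / %d starts",
               path, i, n_blocks, length(sizes), length(starts))
    exon_start <- chrom_start + starts
    exon_end <- exon_start + sizes
    if (any(sizes <= 0L))
      stop_fmt("%s line %d: exon block with non-positive size", path, i)
    if (is.unsorted(exon_start, strictly = TRUE) ||
        any(exon_start[-1L] < exon_end[-n_blocks]))
      stop_fmt("%s line %d: exon blocks unsorted or overlapping", path, i)
    if (exon_end[n_blocks] > chrom_end)
      stop_fmt("%s line %d: blocks extend past chromEnd", path, i)
    out[[i]] <- structure(list(gene_id = f[4L], contig = f[1L], strand = strand,
                               exons = cbind(start = exon_start, end = exon_end)),
                          class = "gene_model")
  }
  out
}

#' Total exonic length of a gene model
#' @param gene A `gene_model`.
#' @return Integer number of exonic bases.
#' @export
gene_length <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  sum(gene$exons[, "end"] - gene$exons[, "start"])
}

# Reference span of a CIGAR string: bases consumed on the reference
# (ops M, D, N, =, X). I, S, H, P consume none.
cigar_ref_span <- function(cigar) {
  if (cigar == "*") return(NA_integer_)
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  if (length(ops) == 0L || sum(nchar(ops)) != nchar(cigar))
    stop_fmt("cannot parse CIGAR string %s", sQuote(cigar))
  lens <- as.integer(sub("[MIDNSHP=X]$", "", ops))
  kinds <- sub("^\\d+", "", ops)
  sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
}

#' Read 5'-end read-start sites from SAM or TSV
#'
#' For SAM input each kept primary alignment contributes the reference
#' position of its 5'-end base: the leftmost aligned base for forward-strand
#' alignments and the rightmost aligned base (leftmost + CIGAR reference
#' span - 1) for reverse-strand alignments. Identical (contig, pos, strand)
#' sites are aggregated with summed counts. The TSV dialect (tab-separated,
#' header `contig pos strand count`, 0-based pos) is passed through and
#' aggregated the same way.
#'
#' Uniqueness filtering for SAM: an alignment is kept when its NH tag equals
#' 1 if the tag is present, otherwise when its mapping quality is at least
#' `min_mapq` (default 255, the usual splice-aligner "unique" value).
#' Secondary, supplementary and unmapped records are always dropped.
#'
#' @param path Input file.
#' @param format `"sam"`, `"tsv"`, or `"auto"` (by file extension).
#' @param min_mapq Minimum mapping quality when no NH tag is present.
#' @param unique_only Apply the uniqueness filter (SAM only).
#' @param mate1_only If `TRUE`, only first-in-pair (or unpaired) reads
#'   contribute; by default both mates do, since priming acts at the 5' end
#'   of each cDNA synthesis event.
#' @return A `data.frame` (class `read_starts`) with columns `contig`,
#'   `pos` (0-based), `strand`, `count`.
#' @export
read_read_starts <- function(path, format = c("auto", "sam", "tsv"),
                             min_mapq = 255L, unique_only = TRUE,
                             mate1_only = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_fmt("input file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "sam") "sam" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "integer",
                                           "character", "integer"))
    need <- c("contig", "pos", "strand", "count")
    if (!all(need %in% names(df)))
      stop_fmt("read-start TSV must have header columns %s",
               paste(need, collapse = ", "))
    if (any(df$count < 1L)) stop_fmt("negative or zero count in %s", path)
    if (any(!df$strand %in% c("+", "-")))
      stop_fmt("strand column must be + or - in %s", path)
    sites <- df[, need]
  } else {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "@")]
    n <- length(lines)
    contig <- character(n); pos <- integer(n); strand <- character(n)
    k <- 0L
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(f) < 11L) stop_fmt("malformed SAM record (fewer than 11 fields)")
      flag <- as.integer(f[2L])
      if (bitwAnd(flag, 0x4L) != 0L) next            # unmapped
      if (bitwAnd(flag, 0x100L) != 0L) next          # secondary
      if (bitwAnd(flag, 0x800L) != 0L) next          # supplementary
      if (mate1_only && bitwAnd(flag, 0x1L) != 0L && bitwAnd(flag, 0x40L) == 0L)
        next
      if (unique_only) {
        nh <- grep("^NH:i:", f[-(1:11)], value = TRUE)
        if (length(nh)) {
          if (as.integer(sub("^NH:i:", "", nh[1L])) != 1L) next
        } else if (as.integer(f[5L]) < min_mapq) next
      }
      p0 <- as.integer(f[4L]) - 1L                   # SAM is 1-based
      rev <- bitwAnd(flag, 0x10L) != 0L
      site <- if (rev) p0 + cigar_ref_span(f[6L]) - 1L else p0
      k <- k + 1L
      contig[k] <- f[3L]; pos[k] <- site; strand[k] <- if (rev) "-" else "+"
    }
    if (k == 0L) {
      sites <- data.frame(contig = character(), pos = integer(),
                          strand = character(), count = integer())
    } else {
      sites <- data.frame(contig = contig[1:k], pos = pos[1:k],
                          strand = strand[1:k], count = 1L)
    }
  }
  out <- aggregate_sites(sites)
  class(out) <- c("read_starts", "data.frame")
  out
}

# Sum counts over identical (contig, pos, strand) keys and sort.
aggregate_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(contig = character(), pos = integer(),
                      strand = character(), count = integer()))
  }
  key <- paste(sites$contig, sites$pos, sites$strand, sep = "\r")
  counts <- rowsum(as.numeric(sites$count), key, reorder = FALSE)
  first <- !duplicated(key)
  out <- data.frame(contig = sites$contig[first], pos = sites$pos[first],
                    strand = sites$strand[first],
                    count = as.integer(counts[match(key[first], rownames(counts))]))
  out <- out[order(out$contig, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write read-start sites in the TSV dialect
#' @param sites A `read_starts` data frame.
#' @param path Output path.
#' @export
write_read_starts <- function(sites, path) {
  utils::write.table(sites[, c("contig", "pos", "strand", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement
#'
#' @param seq Character vector of sequences over {A,C,G,T,N}; N maps to N.
#' @return Reverse-complemented sequences.
#' @examples
#' reverse_complement("AAGT")  # "ACTT"
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character())
  if (any(grepl("[^ACGTNacgtn]", seq)))
    stop_fmt("illegal character: sequences must be over {A,C,G,T,N}")
  empty <- !nzchar(seq)
  out <- seq
  if (any(!empty)) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[!empty]))
    out[!empty] <- as.character(rc)
  }
  out
}

#' Extract the context window around a site
#'
#' Returns the `2w+1`-base genomic window centred on `pos`
#' (`genome[pos-w .. pos+w]`, 0-based inclusive); for minus-strand sites the
#' reverse complement, so the model always sees the priming-proximal
#' orientation. Returns `NULL` when the window runs off the contig or
#' contains an N (the 4-letter model has no N state).
#'
#' @param genome A [genome()] object.
#' @param contig Contig name.
#' @param pos 0-based centre coordinate.
#' @param strand `"+"` or `"-"`.
#' @param w Half-width; the window has length `2w+1`.
#' @return A character scalar, or `NULL` for an invalid window.
#' @export
extract_window <- function(genome, contig, pos, strand, w) {
  check_scalar_number(w, "w", lower = 0)
  s <- extract_windows(genome,
                       data.frame(contig = contig, pos = pos, strand = strand),
                       w)
  if (is.na(s)) NULL else s
}

#' Vectorised context-window extraction
#'
#' @param genome A [genome()] object.
#' @param sites Data frame with columns `contig`, `pos`, `strand`.
#' @param w Window half-width.
#' @return Character vector, one element per site, `NA` for invalid windows.
#' @export
extract_windows <- function(genome, sites, w) {
  stopifnot(inherits(genome, "genome"))
  w <- as.integer(check_scalar_number(w, "w", lower = 0))
  unknown <- setdiff(unique(sites$contig), names(genome))
  if (length(unknown))
    stop_fmt("unknown contig(s): %s", paste(unknown, collapse = ", "))
  clen <- nchar(genome)[sites$contig]
  pos <- as.integer(sites$pos)
  ok <- pos - w >= 0L & pos + w <= clen - 1L
  out <- rep(NA_character_, nrow(sites))
  if (any(ok)) {
    out[ok] <- substr(rep(unclass(genome)[sites$contig[ok]], 1L),
                      pos[ok] - w + 1L, pos[ok] + w + 1L)
    hasN <- grepl("N", out, fixed = TRUE)
    out[hasN] <- NA_character_
    minus <- ok & !is.na(out) & sites$strand == "-"
    if (any(minus)) out[minus] <- reverse_complement(out[minus])
  }
  out
}
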