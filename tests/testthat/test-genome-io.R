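test_that("FASTA reading folds case, keeps record order, rejects duplicates", {
  p <- write_lines_tmp(c(">c1", "acgt"), ".fa")
  g <- read_fasta(p)
  expect_s3_class(g, "genome")
  expect_identical(unclass(g), c(c1 = "ACGT"))

  p2 <- write_lines_tmp(c(">b contig-b", "AAAA", "CCCC", ">a", "GGGG"), ".fa")
  g2 <- read_fasta(p2)
  expect_identical(names(g2), c("b", "a"))       # order preserved, not sorted
  expect_identical(unname(unclass(g2)[1]), "AAAACCCC")  # multi-line concatenated

  p3 <- write_lines_tmp(c(">c1", "ACGT", ">c1", "TTTT"), ".fa")
  expect_error(read_fasta(p3), "duplicate")
  p4 <- write_lines_tmp(c(">c1", "ACQT"), ".fa")
  expect_error(read_fasta(p4), "A,C,G,T,N")
})

test_that("genome round-trips through FASTA", {
  g <- tiny_genome()
  p <- tempfile(fileext = ".fa")
  write_fasta(g, p)
  expect_identical(unclass(read_fasta(p)), unclass(g))
})

test_that("BED12 blocks expand to 0-based half-open exons", {
  p <- write_lines_tmp(bed12_line(chrom_start = 100L, sizes = c(50L, 30L),
                                  starts = c(0L, 100L)), ".bed")
  gm <- read_gene_models(p)
  expect_length(gm, 1L)
  expect_identical(gm[[1]]$exons,
                   cbind(start = c(100L, 200L), end = c(150L, 230L)))
  expect_identical(gene_length(gm[[1]]), 80L)

  p1 <- write_lines_tmp(bed12_line(sizes = 40L, starts = 0L), ".bed")
  expect_identical(nrow(read_gene_models(p1)[[1]]$exons), 1L)
})

test_that("malformed BED12 lines are format errors", {
  # blockCount disagrees with the size/start lists
  bad_count <- sub("\t2\t", "\t3\t", bed12_line())
  expect_error(read_gene_models(write_lines_tmp(bad_count, ".bed")),
               "blockCount")
  # overlapping blocks
  overlap <- bed12_line(sizes = c(50L, 30L), starts = c(0L, 20L))
  expect_error(read_gene_models(write_lines_tmp(overlap, ".bed")),
               "unsorted or overlapping")
  expect_error(read_gene_models(write_lines_tmp("c1\t1\t2\tg", ".bed")),
               "12 fields")
})

test_that("SAM 5'-end sites use leftmost base on + and rightmost on -", {
  p <- write_lines_tmp(c(sam_header(),
                         sam_record(qname = "f", flag = 0L, pos1 = 1000L),
                         sam_record(qname = "r", flag = 16L, pos1 = 1000L)),
                       ".sam")
  s <- read_read_starts(p)
  expect_identical(s$pos[s$strand == "+"], 999L)       # 1-based -> 0-based
  expect_identical(s$pos[s$strand == "-"], 1098L)      # 999 + 100 - 1
  expect_true(all(s$count == 1L))
})

test_that("SAM filtering honours flags, NH tag and MAPQ; sites aggregate", {
  recs <- c(sam_header(),
    sam_record(qname = "a", pos1 = 500L),
    sam_record(qname = "b", pos1 = 500L),                      # duplicate site
    sam_record(qname = "multi", pos1 = 600L, tags = "NH:i:3"), # multimapper
    sam_record(qname = "second", flag = 256L, pos1 = 700L),    # secondary
    sam_record(qname = "lowq", pos1 = 800L, mapq = 10L),       # below min_mapq
    sam_record(qname = "soft", flag = 16L, pos1 = 900L, cigar = "10S80M10S"))
  p <- write_lines_tmp(recs, ".sam")
  s <- read_read_starts(p)
  expect_identical(s$count[s$pos == 499L], 2L)
  expect_false(599L %in% s$pos)
  expect_false(699L %in% s$pos)
  expect_false(799L %in% s$pos)
  # soft clips consume no reference: span 80, site 899 + 80 - 1
  expect_true(978L %in% s$pos[s$strand == "-"])
  # with a permissive min_mapq the low-quality read is kept
  s2 <- read_read_starts(p, min_mapq = 0L)
  expect_true(799L %in% s2$pos)
})

test_that("TSV dialect round-trips and matches the SAM-derived sites", {
  recs <- c(sam_header(),
            sam_record(qname = "a", pos1 = 101L),
            sam_record(qname = "b", pos1 = 101L),
            sam_record(qname = "c", flag = 16L, pos1 = 51L, cigar = "50M"))
  sam <- write_lines_tmp(recs, ".sam")
  s_sam <- read_read_starts(sam)
  tsv <- tempfile(fileext = ".tsv")
  write_read_starts(s_sam, tsv)
  s_tsv <- read_read_starts(tsv)
  expect_identical(as.data.frame(s_sam), as.data.frame(s_tsv))
})

test_that("reverse_complement complements, reverses and involutes", {
  expect_identical(reverse_complement("ACGT"), "ACGT")   # palindrome
  expect_identical(reverse_complement("AAGT"), "ACTT")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("NAC"), "GTN")
  expect_error(reverse_complement("AXGT"), "illegal")
  set.seed(11)
  for (s in rand_seqs(20, 13, seed = 11))
    expect_identical(reverse_complement(reverse_complement(s)), s)
})

test_that("extract_window honours coordinates, strand and boundaries", {
  g <- genome(c(c1 = "AACCGGTTAACCGGTTAACCGGTT"))
  expect_identical(extract_window(g, "c1", 12, "+", 2), "CCGGT")
  expect_identical(extract_window(g, "c1", 12, "-", 2), "ACCGG")
  expect_null(extract_window(g, "c1", 1, "+", 2))       # runs off the start
  expect_null(extract_window(g, "c1", 23, "+", 1))      # runs off the end
  expect_error(extract_window(g, "nope", 5, "+", 1), "unknown contig")
  gn <- genome(c(c1 = "ACGTNACGTACGT"))
  expect_null(extract_window(gn, "c1", 3, "+", 2))      # window contains N
})

test_that("valid windows always have length 2w+1", {
  g <- tiny_genome()
  set.seed(3)
  sites <- data.frame(contig = sample(names(g), 60, replace = TRUE),
                      pos = sample.int(28, 60, replace = TRUE) - 1L,
                      strand = sample(c("+", "-"), 60, replace = TRUE))
  for (w in c(1L, 3L, 5L)) {
    out <- extract_windows(g, sites, w)
    expect_true(all(nchar(out[!is.na(out)]) == 2L * w + 1L))
  }
})
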