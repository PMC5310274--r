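make_gene <- function(id, contig, exons, strand = "+") {
  structure(list(gene_id = id, contig = contig, strand = strand,
                 exons = cbind(start = exons[, 1L], end = exons[, 2L])),
            class = "gene_model")
}

test_that("count_read_starts keeps exonic sites under half-open semantics", {
  gm <- list(make_gene("g1", "c1", cbind(100L, 200L)))
  sites <- data.frame(contig = "c1", pos = c(100L, 199L, 200L, 50L),
                      strand = "+", count = c(1L, 2L, 3L, 4L))
  pc <- count_read_starts(sites, gm)
  expect_identical(sort(pc$sites$pos), c(100L, 199L))  # 200 and 50 outside
  expect_identical(pc$total_mapped, 3L)

  dup <- data.frame(contig = "c1", pos = c(150L, 150L), strand = "+",
                    count = c(2L, 5L))
  pc2 <- count_read_starts(dup, gm)
  expect_identical(pc2$sites$count, 7L)
  expect_identical(pc2$total_mapped, 7L)
})

test_that("foreground sampling is count-weighted with replacement", {
  gm <- list(make_gene("g1", "c1", cbind(0L, 10L)))
  counts <- count_read_starts(
    data.frame(contig = "c1", pos = c(1L, 2L), strand = "+",
               count = c(1L, 3L)), gm)
  n <- 4000L
  fg <- sample_foreground_sites(counts, n, seed = 42)
  expect_identical(nrow(fg), n)
  k <- sum(fg$pos == 2L)
  sigma <- sqrt(n * 0.75 * 0.25)
  expect_lt(abs(k - n * 0.75), 3 * sigma)
  expect_error(sample_foreground_sites(counts, 0), "n")

  single <- count_read_starts(
    data.frame(contig = "c1", pos = 5L, strand = "+", count = 2L), gm)
  expect_true(all(sample_foreground_sites(single, 50, seed = 1)$pos == 5L))
})

test_that("background offsets are nonzero, bounded and reproducible", {
  g <- genome(c(c1 = paste(rep("ACGT", 500), collapse = "")))
  fg <- data.frame(contig = "c1", pos = sample(100:1900, 300, replace = TRUE),
                   strand = "+")
  bg1 <- sample_background_sites(fg, max_offset = 30, genome = g, seed = 7, w = 10)
  bg2 <- sample_background_sites(fg, max_offset = 30, genome = g, seed = 7, w = 10)
  expect_identical(bg1, bg2)
  delta <- bg1$pos - fg$pos
  expect_true(all(delta != 0L))
  expect_true(all(abs(delta) <= 30L))
  expect_identical(nrow(bg1), nrow(fg))
  expect_identical(bg1$strand, fg$strand)
})

test_that("background sites with no valid offset are dropped with a warning", {
  g <- genome(c(tiny = "ACGTACGTACGTACGTACGTA"))  # 21 bp: only pos 10 fits w=10
  fg <- data.frame(contig = "tiny", pos = c(10L, 10L), strand = "+")
  expect_warning(
    bg <- sample_background_sites(fg, max_offset = 5, genome = g, seed = 1, w = 10),
    "dropped")
  expect_identical(nrow(bg), 0L)
})

test_that("context extraction filters boundary windows and keeps 2w+1 lengths", {
  g <- genome(c(c1 = paste(rep("ACGT", 30), collapse = "")))  # 120 bp
  sites <- data.frame(contig = "c1", pos = c(5L, 50L, 60L, 115L), strand = "+")
  cs <- extract_context_sequences(sites, g, w = 10, origin = "foreground")
  expect_identical(cs$pos, c(50L, 60L))    # 5 and 115 are within w of an edge
  expect_true(all(nchar(cs$seq) == 21L))
  expect_true(all(cs$origin == "foreground"))
})

test_that("split_dataset follows proportions with remainder to test", {
  s <- rand_seqs(1000, 5, seed = 5)
  ds <- split_dataset(s, c(0.9, 0.05, 0.05), seed = 9)
  expect_identical(lengths(ds[c("train", "validation", "test")]),
                   c(train = 900L, validation = 50L, test = 50L))
  # partition is disjoint and exhaustive
  expect_setequal(c(ds$train, ds$validation, ds$test), s)
  expect_identical(length(c(ds$train, ds$validation, ds$test)), 1000L)

  ds20 <- split_dataset(rand_seqs(20, 5, seed = 6), c(0.9, 0.05, 0.05), seed = 1)
  expect_identical(lengths(ds20[c("train", "validation", "test")]),
                   c(train = 18L, validation = 1L, test = 1L))
  expect_error(split_dataset(s, c(0.5, 0.5, 0.5)), "proportions")
})

test_that("unbiased simulations give matching fg/bg base compositions", {
  sim <- simulate_dataset(sim_config(pwm = NULL, n_reads = 20000L, seed = 3))
  counts <- count_read_starts(sim$sites, sim$gene_models)
  fg <- sample_foreground_sites(counts, 2000, seed = 31)
  bg <- sample_background_sites(fg, max_offset = 30, genome = sim$genome,
                                seed = 32, w = 10)
  fg_freq <- table(factor(strsplit(paste(
    extract_context_sequences(fg, sim$genome, 10, "foreground")$seq,
    collapse = ""), "")[[1]], levels = BASES))
  bg_freq <- table(factor(strsplit(paste(
    extract_context_sequences(bg, sim$genome, 10, "background")$seq,
    collapse = ""), "")[[1]], levels = BASES))
  expect_lt(max(abs(fg_freq / sum(fg_freq) - bg_freq / sum(bg_freq))), 0.02)
})
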