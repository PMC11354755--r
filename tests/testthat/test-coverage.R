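write_bedgraph <- function(lines) {
  f <- tempfile(fileext = ".bedGraph")
  writeLines(lines, f)
  f
}

test_that("bedGraph intervals are expanded to dense per-nucleotide counts", {
  plus <- write_bedgraph("chrI\t10\t13\t4")
  minus <- write_bedgraph(character(0))
  tr <- load_coverage(plus, minus, c(chrI = 50))
  expect_equal(tr$cov$chrI[["+"]][11:13], c(4, 4, 4))  # 0-based 10,11,12
  expect_equal(sum(tr$cov$chrI[["+"]]), 12)
  expect_equal(sum(tr$cov$chrI[["-"]]), 0)
})

test_that("an empty bedGraph yields an all-zero track and bad input errors", {
  empty <- write_bedgraph(character(0))
  tr <- load_coverage(empty, empty, c(chrI = 30, chrII = 20))
  expect_equal(total_reads(tr), 0)
  expect_length(tr$cov$chrII[["+"]], 20)

  over <- write_bedgraph("chrI\t25\t40\t1")
  expect_error(load_coverage(over, empty, c(chrI = 30)), "beyond")
  unknown <- write_bedgraph("chrX\t0\t5\t1")
  expect_error(load_coverage(unknown, empty, c(chrI = 30)), "chrX")
  expect_error(load_coverage(empty, NULL, c(chrI = 30)), "minus")
})

test_that("BAM reads count once at their 3'-most aligned position", {
  sam <- tempfile(fileext = ".sam")
  # 5 reads, 10M each: + reads end at 1-based pos+9; - reads end at pos
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chrT\tLN:100",
    "r1\t0\tchrT\t5\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r2\t0\tchrT\t5\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r3\t16\tchrT\t21\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r4\t0\tchrT\t31\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
    "r5\t16\tchrT\t41\t60\t10M\t*\t0\t0\tACGTACGTAC\t*"
  ), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  tr <- load_coverage(chrom_sizes = c(chrT = 100), bam = bam)
  # manual tally (0-based): + 3' ends at 13,13,39; - 3' ends at 20,40
  expect_equal(tr$cov$chrT[["+"]][14], 2)
  expect_equal(tr$cov$chrT[["+"]][40], 1)
  expect_equal(tr$cov$chrT[["-"]][21], 1)
  expect_equal(tr$cov$chrT[["-"]][41], 1)
  expect_equal(total_reads(tr), 5)
})

test_that("extract_signal slices strandward windows around an anchor", {
  plus_cov <- seq_len(2000)  # value at 0-based pos p is p + 1
  tr <- make_track(2000, plus = plus_cov, minus = rev(plus_cov))
  g_plus <- make_genes(list(gene_id = "p", strand = "+", start = 900,
                            end = 1001))[1, ]
  # + strand, anchor 1000, window [-2, +2) -> positions 998..1001
  sig <- extract_signal(tr, g_plus, c(-2, 2))
  expect_equal(as.numeric(sig), c(999, 1000, 1001, 1002))
  expect_false(attr(sig, "truncated"))

  g_minus <- make_genes(list(gene_id = "m", strand = "-", start = 1000,
                             end = 1100))[1, ]
  # - strand, anchor 1000, window [-2, +2) -> positions 1002,1001,1000,999
  sig_m <- extract_signal(tr, g_minus, c(-2, 2))
  expect_equal(as.numeric(sig_m), rev(plus_cov)[c(1003, 1002, 1001, 1000)])
})

test_that("windows off the chromosome are NA-truncated and flagged", {
  tr <- make_track(100, plus = rep(1, 100))
  g <- make_genes(list(gene_id = "edge", strand = "+", start = 50,
                       end = 98))[1, ]
  sig <- extract_signal(tr, g, c(-2, 10))
  expect_true(attr(sig, "truncated"))
  expect_equal(sum(is.na(sig)), 7)  # positions 100..106 are off the end
})

test_that("window sums equal a brute-force position loop on random tracks", {
  set.seed(11)
  for (i in 1:20) {
    len <- 3000
    tr <- make_track(len, plus = rpois(len, 2), minus = rpois(len, 2))
    strand <- if (runif(1) < 0.5) "+" else "-"
    anchor <- sample(1200:1800, 1)
    g <- make_genes(list(gene_id = "g", strand = strand,
                         start = anchor - 1000, end = anchor + 1000,
                         polyA_site = anchor))[1, ]
    w <- sort(sample(-800:800, 2))
    if (w[1] == w[2]) w[2] <- w[2] + 1
    sig <- extract_signal(tr, g, w)
    expect_equal(sum(sig), brute_window_sum(tr, g, w[1], w[2]))
  }
})

test_that("a disjoint window tiling conserves the total read count", {
  set.seed(3)
  len <- 1000
  tr <- make_track(len, plus = rpois(len, 3))
  g <- make_genes(list(gene_id = "g", strand = "+", start = 0, end = len,
                       polyA_site = 0))[1, ]
  tiles <- lapply(seq(0, len - 100, by = 100), function(s) c(s, s + 100))
  tiled_sum <- sum(vapply(tiles, function(w) sum(extract_signal(tr, g, w)),
                          numeric(1)))
  expect_equal(tiled_sum, total_reads(tr))
})

test_that("extraction is invariant under coordinate reflection + strand flip", {
  set.seed(5)
  len <- 500
  plus <- rpois(len, 2)
  minus <- rpois(len, 2)
  tr <- make_track(len, plus = plus, minus = minus)
  # reflected track: position p -> len - 1 - p, strands swapped
  tr_ref <- make_track(len, plus = rev(minus), minus = rev(plus))
  g <- make_genes(list(gene_id = "g", strand = "+", start = 100, end = 300,
                       polyA_site = 250))[1, ]
  g_ref <- make_genes(list(gene_id = "g", strand = "-",
                           start = len - 300, end = len - 100,
                           polyA_site = len - 1 - 250))[1, ]
  s1 <- extract_signal(tr, g, c(-50, 80))
  s2 <- extract_signal(tr_ref, g_ref, c(-50, 80))
  expect_equal(as.numeric(s1), as.numeric(s2))
})

test_that("sample sheets load all replicates with metadata", {
  dir <- tempfile()
  dir.create(dir)
  for (f in c("a_p.bg", "a_m.bg", "b_p.bg", "b_m.bg")) {
    writeLines("chrI\t0\t5\t2", file.path(dir, f))
  }
  sheet <- file.path(dir, "samples.tsv")
  writeLines(c("sample_id\tgenotype\treplicate\tplus_path\tminus_path",
               "wt1\tWT\t1\ta_p.bg\ta_m.bg",
               "mut1\tmutant\t1\tb_p.bg\tb_m.bg"), sheet)
  tracks <- load_samples(sheet, c(chrI = 20))
  expect_length(tracks, 2)
  expect_equal(tracks[[2]]$genotype, "mutant")
  expect_equal(total_reads(tracks[[1]]), 20)
})
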