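test_that("GFF3 coordinates are converted to the 0-based half-open convention", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chrI\ttest\tgene\t101\t200\t.\t+\t.\tID=gA",
    "chrI\ttest\tCDS\t111\t190\t.\t+\t0\tID=gA_CDS;Parent=gA",
    "chrI\ttest\tgene\t301\t450\t.\t-\t.\tID=gB",
    "chrI\ttest\tCDS\t311\t440\t.\t-\t0\tID=gB_CDS;Parent=gB",
    "chrII\ttest\tgene\t501\t900\t.\t+\t.\tID=gC",
    "chrII\ttest\tCDS\t501\t900\t.\t+\t0\tID=gC_CDS;Parent=gC"
  ), gff)
  tab <- load_annotation(gff, format = "gff3")
  expect_equal(tab$gene_id, c("gA", "gB", "gC"))
  expect_equal(tab$start[tab$gene_id == "gA"], 100)
  expect_equal(tab$end[tab$gene_id == "gA"], 200)
  expect_equal(tab$cds_start[tab$gene_id == "gA"], 110)
  expect_equal(tab$cds_end[tab$gene_id == "gA"], 190)
  # poly(A) site is the strand-aware last transcribed nucleotide
  expect_equal(tab$polyA_site[tab$gene_id == "gA"], 199)
  expect_equal(tab$polyA_site[tab$gene_id == "gB"], 300)
  expect_equal(tab$length_nt, c(100, 150, 400))
  expect_false(any(tab$cds_missing))
})

test_that("BED6 input is taken as already 0-based half-open", {
  bed <- tempfile(fileext = ".bed")
  writeLines("chrI\t100\t200\tgeneA\t0\t+", bed)
  tab <- load_annotation(bed, format = "bed")
  expect_equal(tab$start, 100)
  expect_equal(tab$end, 200)
  expect_equal(tab$polyA_site, 199)
})

test_that("a poly(A) override table replaces the default 3' end", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chrI\t100\t200\tgeneA\t0\t+",
               "chrI\t300\t500\tgeneB\t0\t-"), bed)
  ov <- tempfile(fileext = ".tsv")
  writeLines("geneA\tchrI\t180\t+", ov)
  tab <- load_annotation(bed, format = "bed", polya_override = ov)
  expect_equal(tab$polyA_site[tab$gene_id == "geneA"], 180)
  expect_equal(tab$polyA_site[tab$gene_id == "geneB"], 300)
})

test_that("BED6 round trip reproduces identical coordinates", {
  genes <- make_genes(
    list(gene_id = "a", strand = "+", start = 50, end = 300),
    list(gene_id = "b", strand = "-", start = 400, end = 1000)
  )
  bed <- tempfile(fileext = ".bed")
  write_annotation_bed(genes, bed)
  back <- load_annotation(bed, format = "bed")
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$gene_id, genes$gene_id)
})

test_that("neighbor distances match the direct subtraction examples", {
  # + strand gene ending at 1000 (3' nt 999), next + gene starting at 1600
  genes <- make_genes(
    list(gene_id = "up", strand = "+", start = 500, end = 1000),
    list(gene_id = "dn", strand = "+", start = 1600, end = 2000)
  )
  d <- neighbor_distances(genes)
  expect_equal(d$distance_nt[d$gene_id == "up"], 600)
  expect_equal(d$distance_nt[d$gene_id == "dn"], Inf)

  # - strand gene with 3' end at 5000, neighbor occupying [4000, 4500)
  genes2 <- make_genes(
    list(gene_id = "g1", strand = "-", start = 5000, end = 5400),
    list(gene_id = "g2", strand = "-", start = 4000, end = 4500)
  )
  d2 <- neighbor_distances(genes2)
  expect_equal(d2$distance_nt[d2$gene_id == "g1"], 500)
})

test_that("overlapping same-strand genes give distance 0, never negative", {
  genes <- make_genes(
    list(gene_id = "a", strand = "+", start = 100, end = 600),
    list(gene_id = "b", strand = "+", start = 400, end = 900)
  )
  d <- neighbor_distances(genes)
  expect_equal(d$distance_nt[d$gene_id == "a"], 0)
  expect_true(all(d$distance_nt >= 0))
})

test_that("distances on a mixed-strand fixture equal the brute-force scan", {
  genes <- make_genes(
    list(gene_id = "a", strand = "+", start = 100, end = 400),
    list(gene_id = "b", strand = "-", start = 600, end = 900),
    list(gene_id = "c", strand = "+", start = 1000, end = 1300),
    list(gene_id = "d", strand = "+", start = 1400, end = 1900),
    list(gene_id = "e", strand = "-", start = 2000, end = 2400),
    list(gene_id = "f", strand = "-", start = 3000, end = 3300)
  )
  d <- neighbor_distances(genes)
  for (i in seq_len(nrow(genes))) {
    expect_equal(d$distance_nt[i], brute_neighbor_distance(genes, i),
                 info = genes$gene_id[i])
  }
})

test_that("neighbor distances are invariant under reflection + strand flip", {
  set.seed(42)
  for (rep_i in 1:5) {
    genes <- random_gene_fixture(8, len = 5000)
    d1 <- neighbor_distances(genes)
    d2 <- neighbor_distances(reflect_genes(genes, 5000))
    expect_equal(d1$distance_nt, d2$distance_nt)
  }
})

test_that("gene table invariants are enforced", {
  bad <- make_genes(list(gene_id = "x", strand = "+", start = 10, end = 5))
  expect_error(validate_gene_table(bad), "start >= end")
  bad2 <- make_genes(list(gene_id = "x", strand = "+", start = 10, end = 50,
                          cds_start = 5, cds_end = 40))
  expect_error(validate_gene_table(bad2), "CDS")
})
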