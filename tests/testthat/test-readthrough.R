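# Build a track with piecewise-constant densities around a poly(A) site.
rti_gene_track <- function(body, down, strand = "+", len = 4000,
                           polyA = 2000, extent = 500) {
  arr <- numeric(len)
  if (strand == "+") {
    arr[(polyA - 1500 + 1):(polyA + 1)] <- body
    arr[(polyA + 2):(polyA + 1 + extent)] <- down
  } else {
    arr[(polyA + 1):(polyA + 1501)] <- body
    arr[(polyA - extent + 1):polyA] <- down
  }
  tr <- if (strand == "+") make_track(len, plus = arr) else
    make_track(len, minus = arr)
  g <- make_genes(list(gene_id = "g", strand = strand,
                       start = if (strand == "+") polyA - 1500 else polyA,
                       end = if (strand == "+") polyA + 1 else polyA + 1501,
                       polyA_site = polyA))[1, ]
  list(track = tr, gene = g)
}

test_that("RTI equals the density ratio on piecewise-constant coverage", {
  # body 10/nt, downstream 2/nt -> (2*450)/(10*450) = 0.2 exactly
  fx <- rti_gene_track(10, 2)
  rec <- compute_rti(fx$track, fx$gene)
  expect_equal(rec$rti, 0.2)
  expect_equal(rec$upstream_reads, 4500)
  expect_equal(rec$downstream_reads, 900)
  expect_true(rec$complete)

  # strand symmetry
  fx_m <- rti_gene_track(10, 2, strand = "-")
  expect_equal(compute_rti(fx_m$track, fx_m$gene)$rti, 0.2)

  # uniform coverage over both windows -> 1.0; zero downstream -> 0.0
  expect_equal(compute_rti(rti_gene_track(7, 7)$track,
                           rti_gene_track(7, 7)$gene)$rti, 1.0)
  fx0 <- rti_gene_track(2, 0)
  rec0 <- compute_rti(fx0$track, fx0$gene)
  expect_equal(rec0$rti, 0)
  expect_equal(rec0$upstream_reads, 900)
})

test_that("RTI is undefined on zero upstream and flagged off-chromosome", {
  fx <- rti_gene_track(0, 2)
  expect_true(is.na(compute_rti(fx$track, fx$gene)$rti))

  tr <- make_track(600, plus = rep(1, 600))
  g <- make_genes(list(gene_id = "g", strand = "+", start = 0, end = 400,
                       polyA_site = 399))[1, ]
  rec <- compute_rti(tr, g)  # upstream window would start at -151
  expect_false(rec$complete)
  expect_true(is.na(rec$rti))

  expect_error(compute_rti(fx$track, fx$gene, exclusion_nt = 0), "positive")
})

test_that("window sums agree with the brute-force oracle on random tracks", {
  set.seed(23)
  for (i in 1:25) {
    len <- 4000
    tr <- make_track(len, plus = rpois(len, 4), minus = rpois(len, 4))
    strand <- if (runif(1) < 0.5) "+" else "-"
    polyA <- sample(1000:3000, 1)
    g <- make_genes(list(gene_id = "g", strand = strand,
                         start = polyA - 900, end = polyA + 900,
                         polyA_site = polyA))[1, ]
    rec <- compute_rti(tr, g)
    up <- brute_window_sum(tr, g, -500, -50)
    down <- brute_window_sum(tr, g, 50, 500)
    expect_equal(rec$upstream_reads, up)
    expect_equal(rec$downstream_reads, down)
  }
})

test_that("RTI is invariant to scaling a replicate's coverage", {
  set.seed(9)
  len <- 4000
  tr <- make_track(len, plus = rpois(len, 5))
  g <- make_genes(list(gene_id = "g", strand = "+", start = 1000, end = 2600,
                       polyA_site = 2500))[1, ]
  r1 <- compute_rti(tr, g)$rti
  r2 <- compute_rti(scale_coverage(tr, 7.3), g)$rti
  expect_equal(r1, r2)
})

test_that("window accounting conserves reads over the +/-500 nt span", {
  set.seed(31)
  len <- 4000
  tr <- make_track(len, plus = rpois(len, 4))
  g <- make_genes(list(gene_id = "g", strand = "+", start = 1000, end = 2501,
                       polyA_site = 2500))[1, ]
  rec <- compute_rti(tr, g)
  excluded <- sum(extract_signal(tr, g, c(-50, 50)))
  span <- sum(extract_signal(tr, g, c(-500, 500)))
  expect_equal(rec$upstream_reads + rec$downstream_reads + excluded, span)
})

test_that("differential calls match the degenerate-case contract", {
  mk <- function(gene, genotype, vals) {
    data.frame(gene_id = gene, sample_id = paste0(genotype, seq_along(vals)),
               genotype = genotype, upstream_reads = 1, downstream_reads = 1,
               rti = vals, complete = TRUE, stringsAsFactors = FALSE)
  }
  # identical replicate vectors -> one-sided p = 0.5, not significant
  rti <- rbind(mk("g1", "WT", c(0.1, 0.2, 0.3)),
               mk("g1", "mutant", c(0.1, 0.2, 0.3)))
  d <- differential_readthrough(rti)
  expect_equal(d$p_value, 0.5)
  expect_false(d$significant)
  expect_equal(d$log2_ratio, 0)

  # zero-variance fold change: WT 0.05 x3, mutant 0.20 x3 -> log2 = 2, p = 0
  rti2 <- rbind(mk("g2", "WT", rep(0.05, 3)),
                mk("g2", "mutant", rep(0.20, 3)))
  d2 <- differential_readthrough(rti2)
  expect_equal(d2$log2_ratio, 2)
  expect_equal(d2$p_value, 0)
  expect_true(d2$degenerate)
  expect_true(d2$significant)

  # replicate minimums: 2 + 2 defined replicates < min_total = 5
  rti3 <- rbind(mk("g3", "WT", c(0.05, 0.06)),
                mk("g3", "mutant", c(0.2, 0.22)))
  d3 <- differential_readthrough(rti3)
  expect_false(d3$significant)
  expect_equal(d3$reason, "insufficient_replicates")
})

test_that("the one-sided Welch p matches the reference implementation", {
  set.seed(77)
  for (i in 1:10) {
    wt <- runif(3, 0.02, 0.1)
    mut <- runif(3, 0.05, 0.4)
    got <- welch_test(mut, wt, "greater")
    ref <- t.test(mut, wt, alternative = "greater", var.equal = FALSE)
    expect_equal(got$p_value, ref$p.value)
    expect_false(got$degenerate)
  }
})

test_that("a simulated readthrough shift is detected with the right effect size", {
  # one gene, true readthrough 0.05 (WT) vs 0.15 (mutant), Poisson noise
  set.seed(101)
  mk_rec <- function(genotype, r, rep_i) {
    fx <- rti_gene_track(10, 0)
    arr <- fx$track$cov$chrT[["+"]]
    arr[1:4000] <- rpois(4000, arr[1:4000])
    down_idx <- (fx$gene$polyA_site + 2):(fx$gene$polyA_site + 501)
    arr[down_idx] <- rpois(length(down_idx), 10 * r)
    tr <- make_track(4000, plus = arr, genotype = genotype,
                     sample_id = paste0(genotype, rep_i))
    compute_rti(tr, fx$gene)
  }
  rti <- rbind(
    do.call(rbind, lapply(1:3, function(i) mk_rec("WT", 0.05, i))),
    do.call(rbind, lapply(1:3, function(i) mk_rec("mutant", 0.15, i)))
  )
  d <- differential_readthrough(rti)
  expect_true(d$significant)
  expect_lt(abs(d$log2_ratio - log2(3)), 0.4)
})

test_that("summaries reduce correctly for constant and single-gene input", {
  mk <- function(gene, genotype, vals) {
    data.frame(gene_id = gene, sample_id = paste0(genotype, seq_along(vals)),
               genotype = genotype, upstream_reads = 1, downstream_reads = 1,
               rti = vals, complete = TRUE, stringsAsFactors = FALSE)
  }
  rti <- rbind(mk("g1", "WT", c(0.1, 0.1)), mk("g1", "mutant", c(0.3, 0.3)))
  d <- differential_readthrough(rti, min_total = 4L)
  s <- summarize_rti(d, rti)
  expect_equal(unname(s$mean_rti), c(0.1, 0.3))
  expect_equal(s$median_rti, s$mean_rti)  # single gene: median = mean
  expect_equal(s$n_genes, 1)

  rti2 <- rbind(rti,
                mk("g2", "WT", c(0.2, 0.2)), mk("g2", "mutant", c(0.4, 0.4)))
  s2 <- summarize_rti(differential_readthrough(rti2, min_total = 4L), rti2)
  expect_equal(unname(s2$mean_rti), c(0.15, 0.35))
  expect_equal(unname(s2$median_rti), c(0.15, 0.35))
})

test_that("type-I error is controlled under the null at small n", {
  # identical generative parameters in both genotypes over 500 genes
  cfg <- simulation_config(n_genes = 500L, r_wt = 0.05, r_mut = 0.05,
                           seed = 19L)
  sim <- simulate_genome(cfg)
  tracks <- simulate_tracks(sim, cfg)
  rti <- rti_table(tracks, sim$genes)
  d <- differential_readthrough(rti)
  expect_lt(mean(d$p_value < 0.05, na.rm = TRUE), 0.08)
  expect_lt(mean(d$significant), 0.08)
})
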