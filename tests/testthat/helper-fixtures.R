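# Shared in-code fixtures and independent brute-force oracles.
# Oracles deliberately use explicit position loops, never the package's
# vectorized window machinery.

make_genes <- function(..., chrom = "chrT") {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r$gene_id, chrom = r$chrom %||% chrom,
               strand = r$strand, start = r$start, end = r$end,
               polyA_site = r$polyA_site %||%
                 (if (r$strand == "+") r$end - 1 else r$start),
               cds_start = r$cds_start %||% r$start,
               cds_end = r$cds_end %||% r$end,
               length_nt = r$end - r$start, cds_missing = FALSE,
               stringsAsFactors = FALSE)
  }))
  class(df) <- c("gene_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Dense uniform-zero track with optional per-strand vectors.
make_track <- function(len, plus = NULL, minus = NULL, chrom = "chrT",
                       sample_id = "s1", genotype = "WT", replicate = 1L) {
  coverage_track(
    stats::setNames(list(list(`+` = plus %||% numeric(len),
                              `-` = minus %||% numeric(len))), chrom),
    sample_id = sample_id, genotype = genotype, replicate = replicate)
}

# Brute-force strandward window sum: position-by-position loop.
brute_window_sum <- function(track, gene, lo, hi) {
  arr <- track$cov[[gene$chrom]][[gene$strand]]
  total <- 0
  for (off in lo:(hi - 1)) {
    pos <- if (gene$strand == "+") gene$polyA_site + off else
      gene$polyA_site - off
    if (pos >= 0 && pos < length(arr)) total <- total + arr[pos + 1]
  }
  total
}

# Brute-force same-strand downstream neighbor distance by pairwise scan.
brute_neighbor_distance <- function(genes, i) {
  best <- Inf
  g <- genes[i, ]
  for (j in seq_len(nrow(genes))) {
    if (j == i) next
    h <- genes[j, ]
    if (h$chrom != g$chrom || h$strand != g$strand) next
    if (g$strand == "+") {
      nt <- h$start:(h$end - 1)
      nt <- nt[nt > g$polyA_site]
    } else {
      nt <- h$start:(h$end - 1)
      nt <- nt[nt < g$polyA_site]
    }
    if (length(nt)) best <- min(best, min(abs(nt - g$polyA_site)) - 1)
  }
  max(best, 0)
}

# Random small gene fixture on one chromosome for property tests;
# overlaps are allowed so the distance-0 branch is exercised.
random_gene_fixture <- function(n, len = 5000) {
  args <- lapply(seq_len(n), function(i) {
    s <- sample.int(len - 300, 1)
    list(gene_id = sprintf("r%02d", i),
         strand = if (stats::runif(1) < 0.5) "+" else "-",
         start = s, end = s + sample(50:250, 1))
  })
  do.call(make_genes, args)
}

# 10-gene filter fixture with planted violations of each criterion and
# boundary cases sitting exactly on the thresholds.
planted_fixture <- function() {
  spec <- list(
    list(id = "ok1",     len = 1000, gap = 800, expr = 3),
    list(id = "shortg",  len = 499,  gap = 800, expr = 3),    # length fail
    list(id = "near",    len = 1000, gap = 300, expr = 3),    # distance fail
    list(id = "silent",  len = 1000, gap = 800, expr = 0.2),  # expression fail
    list(id = "bound_l", len = 500,  gap = 800, expr = 3),    # boundary length
    list(id = "bound_d", len = 1000, gap = 500, expr = 3),    # boundary distance
    list(id = "bound_e", len = 1000, gap = 800, expr = 1.0),  # boundary expr
    list(id = "ok2",     len = 800,  gap = 900, expr = 5),
    list(id = "lowrep",  len = 1000, gap = 800, expr = NA),   # expr in <3 reps
    list(id = "last",    len = 1000, gap = 10000, expr = 3)
  )
  pos <- 1000
  rows <- list()
  for (i in seq_along(spec)) {
    s <- spec[[i]]
    rows[[i]] <- list(gene_id = s$id, strand = "+", start = pos,
                      end = pos + s$len)
    pos <- pos + s$len + s$gap
  }
  genes <- do.call(make_genes, rows)
  len_chr <- pos + 1000
  # deterministic uniform coverage at the planted expression level;
  # "lowrep" reaches 1 read/nt in only 2 of 4 replicates
  tracks <- lapply(1:4, function(r) {
    plus <- numeric(len_chr)
    for (i in seq_along(spec)) {
      s <- spec[[i]]
      e <- if (s$id == "lowrep") { if (r <= 2) 2 else 0.5 } else s$expr
      plus[(genes$start[i] + 1):genes$end[i]] <- e
    }
    make_track(len_chr, plus = plus, sample_id = paste0("s", r),
               genotype = if (r <= 2) "WT" else "mutant", replicate = r)
  })
  list(genes = genes, tracks = tracks)
}

# Two genes (one per strand) with uniform body coverage and an optional
# downstream plateau at `down` times the body rate.
uniform_fixture <- function(rates, down = 0, n_tracks = 1, len = 6000) {
  genes <- make_genes(
    list(gene_id = "u1", strand = "+", start = 500, end = 2001),
    list(gene_id = "u2", strand = "-", start = 3500, end = 5001)
  )
  tracks <- lapply(seq_len(n_tracks), function(k) {
    plus <- numeric(len)
    minus <- numeric(len)
    plus[501:2001] <- rates[1]
    plus[2002:2501] <- down * rates[1]
    minus[3501:5001] <- rates[min(2, length(rates))]
    minus[3001:3500] <- down * rates[min(2, length(rates))]
    make_track(len, plus = plus, minus = minus,
               sample_id = paste0("t", k), replicate = k)
  })
  list(genes = genes, tracks = tracks)
}

# Reflect a gene fixture through the chromosome and flip strands.
reflect_genes <- function(genes, len) {
  out <- genes
  out$start <- len - genes$end
  out$end <- len - genes$start
  out$strand <- ifelse(genes$strand == "+", "-", "+")
  out$polyA_site <- ifelse(out$strand == "+", out$end - 1, out$start)
  out$cds_start <- len - genes$cds_end
  out$cds_end <- len - genes$cds_start
  out
}
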