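#' Synthetic nascent-transcription data with known ground truth
#'
#' The generator emulates the data-generating situation of a strand-
#' specific nascent-RNA 3'-end experiment: per-nucleotide counts are
#' Poisson with mean `body_rate` across each gene body, and past the
#' poly(A) site a readthrough plateau of mean `body_rate * r` extends for
#' `readthrough_extent_nt` nucleotides (optionally decaying with a
#' half-life) before dropping to zero. `r` is the genotype's true
#' readthrough fraction, the quantity the readthrough index estimates.
#' Genes are placed sequentially on one synthetic chromosome with
#' inter-gene spacing drawn from a configurable range, so neighbor
#' distances (and hence filter behavior) are plantable. Everything is
#' deterministic under the configured seed.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults describe the reference simulation used throughout the test
#' suite: 200 well-separated, uniformly expressed genes with body rate 10
#' reads/nt, constant (no-decay) readthrough of fraction 0.05 in the wild
#' type and 0.15 in the mutant over 500 nt, three replicates per
#' genotype.
#'
#' @param n_genes number of genes.
#' @param gene_length_range min/max gene length (nt).
#' @param spacing_range min/max spacing between consecutive genes (nt).
#' @param p_plus probability a gene is on the plus strand.
#' @param body_rate Poisson mean of gene-body coverage (reads/nt).
#' @param r_wt,r_mut true readthrough fraction per genotype, in [0, 1].
#' @param decay_halflife_nt half-life of downstream decay in nt, or
#'   `NULL` for a constant plateau over the readthrough extent.
#' @param readthrough_extent_nt length of the readthrough zone (nt).
#' @param n_replicates replicates per genotype.
#' @param chrom synthetic chromosome name.
#' @param buffer_nt empty sequence before the first and after the last
#'   gene, so every analysis window is on-chromosome.
#' @param seed base RNG seed; replicate tracks use derived sub-seeds.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200L,
                              gene_length_range = c(1000, 2000),
                              spacing_range = c(700, 1200),
                              p_plus = 0.5,
                              body_rate = 10,
                              r_wt = 0.05, r_mut = 0.15,
                              decay_halflife_nt = NULL,
                              readthrough_extent_nt = 500L,
                              n_replicates = 3L,
                              chrom = "chrSim",
                              buffer_nt = 600L,
                              seed = 1L) {
  stopifnot(body_rate >= 0, r_wt >= 0, r_wt <= 1, r_mut >= 0, r_mut <= 1,
            n_replicates >= 1, readthrough_extent_nt >= 0,
            spacing_range[1] <= spacing_range[2],
            gene_length_range[1] <= gene_length_range[2])
  structure(list(n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range,
                 spacing_range = spacing_range, p_plus = p_plus,
                 body_rate = body_rate, r_wt = r_wt, r_mut = r_mut,
                 decay_halflife_nt = decay_halflife_nt,
                 readthrough_extent_nt = as.integer(readthrough_extent_nt),
                 n_replicates = as.integer(n_replicates), chrom = chrom,
                 buffer_nt = as.integer(buffer_nt), seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate gene placements on one chromosome
#'
#' Genes are laid out left to right with spacing drawn uniformly from
#' `spacing_range`, strands assigned independently, and CDS equal to the
#' gene span. Deterministic under `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with `genes` (a `gene_table`), `chrom_sizes` (named
#'   vector) and `truth` (per-gene true readthrough fraction and
#'   expression per genotype).
#' @export
simulate_genome <- function(config) {
  n <- config$n_genes
  if (n == 0L) {
    genes <- data.frame(gene_id = character(0), chrom = character(0),
                        strand = character(0), start = numeric(0),
                        end = numeric(0), polyA_site = numeric(0),
                        cds_start = numeric(0), cds_end = numeric(0),
                        length_nt = numeric(0), cds_missing = logical(0))
    class(genes) <- c("gene_table", "data.frame")
    return(list(genes = genes,
                chrom_sizes = stats::setNames(2L * config$buffer_nt,
                                              config$chrom),
                truth = data.frame(gene_id = character(0),
                                   r_WT = numeric(0), r_mutant = numeric(0),
                                   expression = numeric(0))))
  }
  with_seed(derive_seed(config$seed, 1L), {
    lens <- round(stats::runif(n, config$gene_length_range[1],
                               config$gene_length_range[2]))
    gaps <- round(stats::runif(n, config$spacing_range[1],
                               config$spacing_range[2]))
    strands <- ifelse(stats::runif(n) < config$p_plus, "+", "-")
    starts <- numeric(n)
    starts[1] <- config$buffer_nt
    if (n > 1) {
      for (i in 2:n) starts[i] <- starts[i - 1] + lens[i - 1] + gaps[i - 1]
    }
    ends <- starts + lens
    chrom_len <- ends[n] + config$buffer_nt
    genes <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n)),
      chrom = config$chrom,
      strand = strands,
      start = starts, end = ends,
      polyA_site = ifelse(strands == "+", ends - 1, starts),
      cds_start = starts, cds_end = ends,
      length_nt = lens,
      cds_missing = FALSE,
      stringsAsFactors = FALSE
    )
    class(genes) <- c("gene_table", "data.frame")
    validate_gene_table(genes)
    truth <- data.frame(gene_id = genes$gene_id, r_WT = config$r_wt,
                        r_mutant = config$r_mut,
                        expression = config$body_rate,
                        stringsAsFactors = FALSE)
    list(genes = genes,
         chrom_sizes = stats::setNames(chrom_len, config$chrom),
         truth = truth)
  })
}

## Downstream decay profile g(d) over offsets d = 0..extent-1.
readthrough_profile <- function(config) {
  d <- seq_len(config$readthrough_extent_nt) - 1
  if (is.null(config$decay_halflife_nt)) rep(1, length(d))
  else 2^(-d / config$decay_halflife_nt)
}

#' Simulate one replicate coverage track
#'
#' Per nucleotide of a gene body the count is Poisson(`body_rate`); over
#' the `readthrough_extent_nt` nucleotides strandward of the poly(A) site
#' it is Poisson(`body_rate * r * g(d)`) with `g` the (constant or
#' exponentially decaying) readthrough profile; elsewhere zero. Signals
#' of overlapping same-strand genes add.
#'
#' @param sim output of [simulate_genome()].
#' @param config the same [simulation_config()].
#' @param genotype `"WT"` or `"mutant"`.
#' @param replicate replicate number (drives the sub-seed).
#' @return a `coverage_track`.
#' @export
simulate_coverage <- function(sim, config, genotype = "WT", replicate = 1L) {
  genes <- sim$genes
  L <- unname(sim$chrom_sizes[config$chrom])
  r_col <- if (genotype == "WT") "r_WT" else "r_mutant"
  stream <- 10L + replicate + if (genotype == "WT") 0L else 500L
  prof <- readthrough_profile(config)
  with_seed(derive_seed(config$seed, stream), {
    cov <- list(`+` = numeric(L), `-` = numeric(L))
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      s <- g$strand
      body_idx <- (g$start + 1):g$end          # 1-based indices
      cov[[s]][body_idx] <- cov[[s]][body_idx] +
        stats::rpois(length(body_idx), config$body_rate)
      r <- sim$truth[[r_col]][sim$truth$gene_id == g$gene_id]
      if (config$readthrough_extent_nt > 0 && r > 0) {
        offs <- seq_len(config$readthrough_extent_nt)   # 1..extent past pA
        pos <- if (s == "+") g$polyA_site + offs else g$polyA_site - offs
        keep <- pos >= 0 & pos < L
        if (any(keep)) {
          cov[[s]][pos[keep] + 1] <- cov[[s]][pos[keep] + 1] +
            stats::rpois(sum(keep), config$body_rate * r * prof[keep])
        }
      }
    }
    new_coverage_track(
      sample_id = sprintf("%s_rep%d", genotype, replicate),
      genotype = genotype, replicate = replicate,
      chrom_sizes = sim$chrom_sizes,
      cov = stats::setNames(list(cov), config$chrom)
    )
  })
}

#' Simulate all replicate tracks of both genotypes
#'
#' @param sim output of [simulate_genome()].
#' @param config a [simulation_config()].
#' @return list of `coverage_track`s, WT replicates first.
#' @export
simulate_tracks <- function(sim, config) {
  c(lapply(seq_len(config$n_replicates), function(r) {
      simulate_coverage(sim, config, "WT", r)
    }),
    lapply(seq_len(config$n_replicates), function(r) {
      simulate_coverage(sim, config, "mutant", r)
    }))
}

## Write one dense strand vector as bedGraph (zero runs omitted).
dense_to_bedgraph <- function(vec, chrom, path) {
  r <- rle(vec)
  ends <- cumsum(r$lengths)            # 0-based half-open interval ends
  starts <- ends - r$lengths
  keep <- r$values != 0
  if (any(keep)) {
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = starts[keep] + 1L, end = ends[keep]),
      score = r$values[keep]
    )
  } else {
    gr <- GenomicRanges::GRanges(score = numeric(0))
  }
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a full simulated experiment to disk
#'
#' Emits exactly the formats the pipeline reads: GFF3 annotation (gene +
#' CDS features), chrom.sizes, a bedGraph pair per replicate, a sample
#' sheet TSV and a ground-truth JSON.
#'
#' @param config a [simulation_config()].
#' @param outdir output directory (created if needed).
#' @return list with `paths` (named file paths), `sim` (genome +
#'   truth) and `tracks` (in-memory coverage).
#' @export
simulate_experiment <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  ann <- file.path(outdir, "annotation.gff3")
  write_annotation_gff3(sim$genes, ann)
  cs <- file.path(outdir, "chrom.sizes")
  utils::write.table(data.frame(names(sim$chrom_sizes),
                                unname(sim$chrom_sizes)),
                     cs, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  tracks <- simulate_tracks(sim, config)
  sheet <- do.call(rbind, lapply(tracks, function(tr) {
    plus <- sprintf("%s_plus.bedGraph", tr$sample_id)
    minus <- sprintf("%s_minus.bedGraph", tr$sample_id)
    dense_to_bedgraph(tr$cov[[config$chrom]][["+"]], config$chrom,
                      file.path(outdir, plus))
    dense_to_bedgraph(tr$cov[[config$chrom]][["-"]], config$chrom,
                      file.path(outdir, minus))
    data.frame(sample_id = tr$sample_id, genotype = tr$genotype,
               replicate = tr$replicate, plus_path = plus,
               minus_path = minus, stringsAsFactors = FALSE)
  }))
  sheet_path <- file.path(outdir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(outdir, "truth.json")
  jsonlite::write_json(list(config = unclass(config), truth = sim$truth),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  list(paths = list(annotation = ann, chrom_sizes = cs,
                    sample_sheet = sheet_path, truth = truth_path,
                    outdir = outdir),
       sim = sim, tracks = tracks)
}

#' Write gene models as GFF3 (gene + CDS features)
#'
#' @param genes gene table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(genes, path) {
  n <- nrow(genes)
  if (n == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id
  )
  gene_gr$Parent <- IRanges::CharacterList(rep(list(character(0)), n))
  gene_gr$phase <- NA_integer_
  has_cds <- !genes$cds_missing
  cds_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom[has_cds],
    ranges = IRanges::IRanges(start = genes$cds_start[has_cds] + 1L,
                              end = genes$cds_end[has_cds]),
    strand = genes$strand[has_cds],
    type = "CDS", ID = paste0(genes$gene_id[has_cds], "_CDS")
  )
  cds_gr$Parent <- IRanges::CharacterList(as.list(genes$gene_id[has_cds]))
  cds_gr$phase <- 0L
  gr <- c(gene_gr, cds_gr)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Simulate a paired spectral-count table
#'
#' Counts are Poisson with mean `abundance * length_aa * scale`; the bait
#' abundance is identical in both genotypes, so genotype effects planted
#' on other proteins appear as BNSAF changes.
#'
#' @param proteins data frame with `protein_id`, `length_aa`,
#'   `abundance_wt`, `abundance_mut`; defaults to a TFIIB purification
#'   panel with an 80% decline planted on CF1 and Rat1 subunits.
#' @param bait_id bait protein id.
#' @param n_pairs paired replicates per genotype.
#' @param scale counts per unit abundance per residue.
#' @param fraction fraction label.
#' @param seed RNG seed.
#' @return long spectral-count data frame for [compute_bnsaf()].
#' @export
simulate_spectral_counts <- function(proteins = NULL, bait_id = "TFIIB",
                                     n_pairs = 4L, scale = 1,
                                     fraction = "chromatin", seed = 1L) {
  if (is.null(proteins)) {
    term <- c("Rna14", "Rna15", "Pcf11", "Clp1", "Hrp1", "Rat1", "Rai1")
    proteins <- data.frame(
      protein_id = c(bait_id, term),
      length_aa = c(345, 677, 296, 626, 445, 534, 1006, 387),
      abundance_wt = c(1, rep(0.5, length(term))),
      abundance_mut = c(1, rep(0.5 * 0.2, length(term))),
      stringsAsFactors = FALSE
    )
  }
  stopifnot(all(proteins$abundance_wt >= 0), all(proteins$abundance_mut >= 0))
  with_seed(derive_seed(seed, 31L), {
    rows <- list()
    for (rep_i in seq_len(n_pairs)) {
      for (gt in c("WT", "mutant")) {
        ab <- if (gt == "WT") proteins$abundance_wt else proteins$abundance_mut
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = proteins$protein_id,
          protein_length_aa = proteins$length_aa,
          spectral_counts = stats::rpois(nrow(proteins),
                                         ab * proteins$length_aa * scale),
          sample_id = sprintf("%s_%s_rep%d", fraction, gt, rep_i),
          genotype = gt, fraction = fraction, replicate = rep_i,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a ChIP measurement table with a planted occupancy decline
#'
#' True occupancy is 1 in WT and `1 - decline` in the mutant; raw chip,
#' input and RNAPII signals carry independent log-normal technical noise
#' so the double normalization is exercised.
#'
#' @param factors factor names.
#' @param gene_ids genes assayed.
#' @param decline planted fractional occupancy decline in the mutant.
#' @param n_replicates replicates per genotype.
#' @param noise_cv coefficient of variation of the log-normal noise.
#' @param seed RNG seed.
#' @return ChIP measurement data frame for [chip_decline_table()].
#' @export
simulate_chip_table <- function(factors = c("Pta1", "Rna15", "Rat1"),
                                gene_ids = c("BLM10", "HEM3", "KAP123",
                                             "SUR1"),
                                decline = 0.9, n_replicates = 3L,
                                noise_cv = 0.1, seed = 1L) {
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(derive_seed(seed, 41L), {
    grid <- expand.grid(factor = factors, gene_id = gene_ids,
                        genotype = c("WT", "mutant"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    occ <- ifelse(grid$genotype == "WT", 1, 1 - decline)
    n <- nrow(grid)
    input <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    polII_input <- stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    polII_ratio <- 2 * stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    grid$polII_input_signal <- polII_input
    grid$polII_chip_signal <- polII_ratio * polII_input
    grid$input_signal <- input
    grid$chip_signal <- occ * polII_ratio * input *
      stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    grid$amplicon <- "terminator"
    grid[, c("factor", "gene_id", "amplicon", "genotype", "replicate",
             "chip_signal", "input_signal", "polII_chip_signal",
             "polII_input_signal")]
  })
}

#' Simulate a TRO measurement table
#'
#' Gene-body signal is equal in both genotypes; downstream (RT1..RT5)
#' nascent signal is near zero in WT and elevated in the mutant,
#' emulating a terminator readthrough defect read out by run-on RT-PCR.
#'
#' @param gene_ids genes assayed.
#' @param wt_downstream,mut_downstream true downstream signal relative to
#'   the body signal per genotype.
#' @param n_replicates replicates per genotype.
#' @param noise_cv log-normal noise CV.
#' @param seed RNG seed.
#' @return TRO measurement data frame for [tro_decline_table()].
#' @export
simulate_tro_table <- function(gene_ids = c("BLM10", "HEM3", "SEN1", "CBK1",
                                            "KAP123", "SUR1"),
                               wt_downstream = 0.05, mut_downstream = 0.5,
                               n_replicates = 3L, noise_cv = 0.15,
                               seed = 1L) {
  sdlog <- sqrt(log(1 + noise_cv^2))
  primers <- c("body", paste0("RT", 1:5))
  with_seed(derive_seed(seed, 51L), {
    grid <- expand.grid(gene_id = gene_ids, primer_id = primers,
                        genotype = c("WT", "mutant"),
                        replicate = seq_len(n_replicates),
                        stringsAsFactors = FALSE)
    level <- ifelse(grid$primer_id == "body", 1,
                    ifelse(grid$genotype == "WT", wt_downstream,
                           mut_downstream))
    n <- nrow(grid)
    grid$control_18S <- 100 * stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    grid$signal <- level * grid$control_18S *
      stats::rlnorm(n, meanlog = 0, sdlog = sdlog)
    grid
  })
}
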