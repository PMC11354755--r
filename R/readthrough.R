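#' Readthrough index and differential readthrough calling
#'
#' The readthrough index (RTI) of a gene in one replicate is the ratio of
#' nascent-RNA 3'-end reads in a downstream window past the poly(A) site
#' to reads in an upstream window inside the gene body, excluding a zone
#' directly flanking the cleavage site. With the defaults
#' (`exclusion_nt = 50`, `window_nt = 450`) the downstream window spans
#' strandward offsets +50..+500 and the upstream window -500..-50, each
#' 450 nt wide. Efficient termination gives RTI near 0; a terminator
#' readthrough defect raises it.
#'
#' @name readthrough_stats
NULL

#' Readthrough index of one gene in one replicate
#'
#' Downstream window: strandward offsets `[exclusion, exclusion + window)`
#' from the poly(A) site; upstream window: `[-exclusion - window,
#' -exclusion)`. Sums are strand-matched. If either window runs off the
#' chromosome the record is flagged incomplete and excluded downstream.
#' RTI is undefined (NA) when the upstream sum is 0.
#'
#' @param track a `coverage_track`.
#' @param gene one-row gene table entry.
#' @param exclusion_nt excluded zone half-width around the poly(A) site.
#' @param window_nt window width in nt.
#' @return one-row data frame: `gene_id`, `sample_id`, `genotype`,
#'   `upstream_reads`, `downstream_reads`, `rti`, `complete`.
#' @export
compute_rti <- function(track, gene, exclusion_nt = 50, window_nt = 450) {
  if (exclusion_nt <= 0 || window_nt <= 0) {
    stop("exclusion_nt and window_nt must be positive (windows must not overlap)")
  }
  up <- extract_signal(track, gene,
                       c(-exclusion_nt - window_nt, -exclusion_nt))
  down <- extract_signal(track, gene,
                         c(exclusion_nt, exclusion_nt + window_nt))
  complete <- !attr(up, "truncated") && !attr(down, "truncated")
  u <- sum(up)
  d <- sum(down)
  rti <- if (complete && !is.na(u) && u > 0) d / u else NA_real_
  data.frame(gene_id = gene$gene_id, sample_id = track$sample_id,
             genotype = track$genotype, upstream_reads = u,
             downstream_reads = d, rti = rti, complete = complete,
             stringsAsFactors = FALSE)
}

#' RTI for every gene and every replicate
#'
#' @param tracks list of `coverage_track` objects.
#' @param genes gene table (usually the filtered set).
#' @inheritParams compute_rti
#' @return data frame of per-gene per-replicate RTI records.
#' @export
rti_table <- function(tracks, genes, exclusion_nt = 50, window_nt = 450) {
  do.call(rbind, lapply(tracks, function(tr) {
    do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      compute_rti(tr, genes[i, ], exclusion_nt, window_nt)
    }))
  }))
}

#' Differential readthrough between genotypes
#'
#' Per gene, compares replicate RTI values of the mutant against the wild
#' type with a one-sided unequal-variance (Welch) t-test (alternative:
#' mutant > WT). The fold change is the log2 ratio of per-genotype mean
#' RTIs. A gene is significant when `p < alpha`, `log2_ratio >
#' log2_fc_threshold`, and the replicate minimums are met. Replicates
#' with undefined RTI (zero upstream reads or a truncated window) are
#' dropped, not imputed; genes that then fail the minimums are reported
#' with `significant = FALSE` and a reason code. When both genotypes have
#' zero variance the limiting p-value is reported (0 / 0.5 / 1 by the
#' sign of the mean difference) and the gene is flagged degenerate. A
#' Benjamini-Hochberg adjusted column is emitted for reference but does
#' not drive the significance flag.
#'
#' @param rti data frame from [rti_table()] covering both genotypes.
#' @param wt,mutant genotype labels in `rti$genotype`.
#' @param alpha significance level on the raw p-value.
#' @param log2_fc_threshold minimum log2 RTI ratio (mutant/WT).
#' @param min_total minimum total replicates with defined RTI.
#' @param min_per_group minimum defined replicates per genotype.
#' @return data frame with one row per gene: means, `log2_ratio`,
#'   `p_value`, `q_value`, `n_wt`, `n_mut`, `significant`, `degenerate`,
#'   `reason`.
#' @export
differential_readthrough <- function(rti, wt = "WT", mutant = "mutant",
                                     alpha = 0.05, log2_fc_threshold = 1.0,
                                     min_total = 5L, min_per_group = 2L) {
  rti <- rti[rti$complete & !is.na(rti$rti), , drop = FALSE]
  out <- lapply(unique(rti$gene_id), function(g) {
    x <- rti[rti$gene_id == g, ]
    v_wt <- x$rti[x$genotype == wt]
    v_mut <- x$rti[x$genotype == mutant]
    n_wt <- length(v_wt)
    n_mut <- length(v_mut)
    mean_wt <- if (n_wt) mean(v_wt) else NA_real_
    mean_mut <- if (n_mut) mean(v_mut) else NA_real_
    l2 <- if (!is.na(mean_wt) && !is.na(mean_mut) && mean_wt > 0) {
      log2(mean_mut / mean_wt)
    } else NA_real_
    enough <- n_wt >= min_per_group && n_mut >= min_per_group &&
      (n_wt + n_mut) >= min_total
    if (!enough) {
      return(data.frame(gene_id = g, mean_rti_wt = mean_wt,
                        mean_rti_mut = mean_mut, log2_ratio = l2,
                        p_value = NA_real_, n_wt = n_wt, n_mut = n_mut,
                        significant = FALSE, degenerate = FALSE,
                        reason = "insufficient_replicates",
                        stringsAsFactors = FALSE))
    }
    tt <- welch_test(v_mut, v_wt, alternative = "greater")
    sig <- tt$p_value < alpha && !is.na(l2) && l2 > log2_fc_threshold
    data.frame(gene_id = g, mean_rti_wt = mean_wt, mean_rti_mut = mean_mut,
               log2_ratio = l2, p_value = tt$p_value, n_wt = n_wt,
               n_mut = n_mut, significant = sig, degenerate = tt$degenerate,
               reason = "ok", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out
}

#' Genome-wide RTI summary
#'
#' Per-gene RTI is first averaged over replicates within each genotype;
#' the genome-wide mean and median are then taken over genes (unweighted).
#' The mean comparison is tested with a two-sided paired t-test across
#' genes; the median display comparison with a two-sided unequal-variance
#' t-test.
#'
#' @param diff output of [differential_readthrough()].
#' @param rti output of [rti_table()].
#' @param wt,mutant genotype labels.
#' @return list with per-genotype `mean_rti` and `median_rti`,
#'   `fraction_significant`, `n_genes`, `p_paired` and `p_welch`.
#' @export
summarize_rti <- function(diff, rti, wt = "WT", mutant = "mutant") {
  rti <- rti[rti$complete & !is.na(rti$rti), , drop = FALSE]
  agg <- stats::aggregate(rti ~ gene_id + genotype, data = rti, FUN = mean)
  g_wt <- agg[agg$genotype == wt, ]
  g_mut <- agg[agg$genotype == mutant, ]
  common <- intersect(g_wt$gene_id, g_mut$gene_id)
  if (!length(common)) stop("no genes with defined RTI in both genotypes")
  v_wt <- g_wt$rti[match(common, g_wt$gene_id)]
  v_mut <- g_mut$rti[match(common, g_mut$gene_id)]
  paired <- if (length(common) >= 2) {
    # constant paired differences leave the statistic undefined -> NA
    tryCatch(stats::t.test(v_mut, v_wt, paired = TRUE)$p.value,
             error = function(e) NA_real_)
  } else NA_real_
  welch <- if (length(common) >= 2) {
    welch_test(v_mut, v_wt, alternative = "two.sided")$p_value
  } else NA_real_
  list(
    mean_rti = c(stats::setNames(mean(v_wt), wt),
                 stats::setNames(mean(v_mut), mutant)),
    median_rti = c(stats::setNames(stats::median(v_wt), wt),
                   stats::setNames(stats::median(v_mut), mutant)),
    fraction_significant = mean(diff$significant),
    n_genes = length(common),
    p_paired = paired,
    p_welch = welch
  )
}

#' Volcano-style scatter data (log2 RTI ratio vs -log10 p)
#'
#' @param diff output of [differential_readthrough()].
#' @return data frame with `gene_id`, `log2_ratio`, `neg_log10_p`,
#'   `significant`.
#' @export
volcano_data <- function(diff) {
  data.frame(gene_id = diff$gene_id, log2_ratio = diff$log2_ratio,
             neg_log10_p = -log10(diff$p_value),
             significant = diff$significant, stringsAsFactors = FALSE)
}
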