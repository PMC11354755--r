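#' Bait-normalized spectral abundance factors (BNSAF)
#'
#' Affinity-purification mass spectrometry reports spectral counts per
#' protein. The spectral abundance factor (SAF) divides a protein's
#' counts by its length in amino acids, removing the length bias of
#' spectral counting. Normalizing each protein's SAF by the SAF of the
#' bait (here TFIIB) in the same purification yields the bait-normalized
#' SAF (BNSAF), which is comparable across purifications regardless of
#' overall yield: the bait's BNSAF is exactly 1 in every sample by
#' construction. Chromatin and soluble fractions are analyzed separately
#' and never merged.
#'
#' @name proteomics_bnsaf
NULL

#' Spectral abundance factor
#'
#' @param spectral_counts non-negative spectral counts (vectorized).
#' @param protein_length_aa protein length in amino acids (> 0).
#' @return `spectral_counts / protein_length_aa`.
#' @export
compute_saf <- function(spectral_counts, protein_length_aa) {
  if (any(protein_length_aa <= 0)) stop("protein length must be > 0")
  if (any(spectral_counts < 0)) stop("negative spectral counts")
  spectral_counts / protein_length_aa
}

#' Subunit-to-complex map for the yeast termination machinery
#'
#' CF1: Rna14, Rna15, Pcf11, Clp1, Hrp1. Rat1: Rat1, Rai1. CPF: core
#' subunits. GTF: general transcription factor subunits (TFIID, TFIIA,
#' TFIIF) used as a non-termination comparison group.
#'
#' @return named character vector mapping protein id to complex label.
#' @export
termination_complexes <- function() {
  map <- c(
    Rna14 = "CF1", Rna15 = "CF1", Pcf11 = "CF1", Clp1 = "CF1", Hrp1 = "CF1",
    Rat1 = "Rat1", Rai1 = "Rat1",
    Pta1 = "CPF", Ssu72 = "CPF", Ysh1 = "CPF", Cft1 = "CPF", Cft2 = "CPF",
    Pap1 = "CPF", Pfs2 = "CPF", Fip1 = "CPF", Mpe1 = "CPF", Pti1 = "CPF",
    Ref2 = "CPF", Swd2 = "CPF", Glc7 = "CPF", Syc1 = "CPF",
    Toa1 = "GTF", Toa2 = "GTF", Tfg1 = "GTF", Tfg2 = "GTF",
    Taf1 = "GTF", Taf2 = "GTF", Taf3 = "GTF", Taf4 = "GTF", Taf5 = "GTF",
    Taf6 = "GTF", Taf7 = "GTF", Taf8 = "GTF", Taf9 = "GTF", Taf10 = "GTF",
    Taf11 = "GTF", Taf12 = "GTF", Taf13 = "GTF", Taf14 = "GTF"
  )
  map
}

#' BNSAF per protein per sample
#'
#' Expects a long spectral-count table with one row per (protein,
#' sample): columns `protein_id`, `protein_length_aa`, `spectral_counts`,
#' `sample_id`, `genotype`, `fraction`, `replicate`. When
#' `protein_length_aa` is absent a counts-only mode is used
#' (`bnsaf = counts / bait counts`) and flagged in the result.
#'
#' @param table spectral-count data frame.
#' @param bait_id bait protein id (default `"TFIIB"`).
#' @return data frame with one row per (protein, sample): `bnsaf`,
#'   `complex_label`, `mode` (`"saf"` or `"counts"`), plus the input keys.
#' @export
compute_bnsaf <- function(table, bait_id = "TFIIB") {
  need <- c("protein_id", "spectral_counts", "sample_id", "genotype",
            "fraction", "replicate")
  if (!all(need %in% names(table))) {
    stop("spectral-count table must have columns: ",
         paste(need, collapse = ", "))
  }
  has_len <- "protein_length_aa" %in% names(table)
  mode <- if (has_len) "saf" else "counts"
  samples <- unique(table$sample_id)
  out <- lapply(samples, function(s) {
    x <- table[table$sample_id == s, , drop = FALSE]
    bait <- x[x$protein_id == bait_id, , drop = FALSE]
    if (nrow(bait) != 1L) stop("bait ", bait_id, " not found once in sample ", s)
    if (bait$spectral_counts <= 0) {
      stop("bait has zero counts in sample ", s, "; sample rejected")
    }
    abun <- if (has_len) compute_saf(x$spectral_counts, x$protein_length_aa)
            else x$spectral_counts
    bait_abun <- if (has_len) compute_saf(bait$spectral_counts,
                                          bait$protein_length_aa)
                 else bait$spectral_counts
    x$bnsaf <- abun / bait_abun
    x
  })
  out <- do.call(rbind, out)
  cx <- termination_complexes()
  out$complex_label <- ifelse(out$protein_id %in% names(cx),
                              cx[out$protein_id], "other")
  out$complex_label[out$protein_id == bait_id] <- "bait"
  out$mode <- mode
  out
}

#' Per-protein genotype comparison of BNSAF (paired replicates)
#'
#' Replicates are paired by `replicate` index across genotypes; a
#' two-sided paired t-test is applied per protein within each fraction.
#' Percent change is `100 * (mean_mut - mean_wt) / mean_wt`. When all
#' paired differences are zero the test is degenerate: p is reported as 1
#' and flagged.
#'
#' @param bnsaf data frame from [compute_bnsaf()].
#' @param wt,mutant genotype labels.
#' @return data frame per (protein, fraction): means, `percent_change`,
#'   `p_value`, `degenerate`, `complex_label`.
#' @export
compare_genotypes <- function(bnsaf, wt = "WT", mutant = "mutant") {
  keys <- unique(bnsaf[, c("protein_id", "fraction")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    x <- bnsaf[bnsaf$protein_id == keys$protein_id[i] &
                 bnsaf$fraction == keys$fraction[i], , drop = FALSE]
    xw <- x[x$genotype == wt, ]
    xm <- x[x$genotype == mutant, ]
    reps <- sort(intersect(xw$replicate, xm$replicate))
    if (length(reps) < length(unique(c(xw$replicate, xm$replicate)))) {
      stop("unpaired replicate for protein ", keys$protein_id[i],
           " (fraction ", keys$fraction[i], ")")
    }
    vw <- xw$bnsaf[match(reps, xw$replicate)]
    vm <- xm$bnsaf[match(reps, xm$replicate)]
    d <- vm - vw
    degen <- stats::sd(d) == 0
    p <- if (degen) {
      if (all(d == 0)) 1 else 0
    } else stats::t.test(vm, vw, paired = TRUE)$p.value
    mw <- mean(vw)
    mm <- mean(vm)
    data.frame(protein_id = keys$protein_id[i], fraction = keys$fraction[i],
               complex_label = x$complex_label[1],
               mean_bnsaf_wt = mw, mean_bnsaf_mut = mm,
               percent_change = if (mw > 0) 100 * (mm - mw) / mw else NA_real_,
               p_value = p, n_pairs = length(reps), degenerate = degen,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Complex-level summary of BNSAF changes
#'
#' Averages member-protein percent changes per complex and fraction; the
#' complex-level decline always lies between the member extremes.
#'
#' @param comparison data frame from [compare_genotypes()].
#' @return data frame per (complex, fraction) with mean percent change,
#'   member count and member range.
#' @export
complex_summary <- function(comparison) {
  x <- comparison[!is.na(comparison$percent_change), , drop = FALSE]
  keys <- unique(x[, c("complex_label", "fraction")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    m <- x[x$complex_label == keys$complex_label[i] &
             x$fraction == keys$fraction[i], ]
    data.frame(complex_label = keys$complex_label[i],
               fraction = keys$fraction[i],
               mean_percent_change = mean(m$percent_change),
               min_percent_change = min(m$percent_change),
               max_percent_change = max(m$percent_change),
               n_proteins = nrow(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
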