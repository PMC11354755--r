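#' ChIP occupancy and TRO signal normalization
#'
#' Factor ChIP signal is normalized twice: first by the input signal (to
#' correct for chromatin amount and amplicon efficiency) and then by the
#' equally input-normalized RNAPII ChIP signal in the same region, so
#' occupancy reflects factor recruitment per transcribing polymerase
#' rather than transcription level. Transcription run-on (TRO) signal is
#' expressed relative to the 18S rRNA control of the same reaction.
#'
#' @name targeted_assays
NULL

#' Input- and RNAPII-normalized ChIP occupancy
#'
#' `(chip / input) / (polII_chip / polII_input)`; all four raw signals
#' must be positive. Vectorized over measurements; a zero or negative
#' denominator raises an error naming the offending measurement.
#'
#' @param chip_signal,input_signal factor ChIP and its input.
#' @param polII_chip_signal,polII_input_signal RNAPII ChIP and its input.
#' @param label optional measurement labels used in error messages.
#' @return numeric occupancy values (>= 0).
#' @export
chip_occupancy <- function(chip_signal, input_signal, polII_chip_signal,
                           polII_input_signal, label = NULL) {
  label <- label %||% seq_along(chip_signal)
  bad <- input_signal <= 0 | polII_input_signal <= 0 | polII_chip_signal <= 0
  if (any(bad)) {
    stop("non-positive normalizer signal in measurement(s): ",
         paste(label[bad], collapse = ", "))
  }
  (chip_signal / input_signal) / (polII_chip_signal / polII_input_signal)
}

#' TRO nascent signal relative to the 18S control
#'
#' @param signal nascent RT-PCR signal (>= 0).
#' @param control_18S 18S control signal (> 0).
#' @param label optional labels for error messages.
#' @return `signal / control_18S`.
#' @export
tro_signal <- function(signal, control_18S, label = NULL) {
  label <- label %||% seq_along(signal)
  if (any(control_18S <= 0)) {
    stop("non-positive 18S control in measurement(s): ",
         paste(label[control_18S <= 0], collapse = ", "))
  }
  signal / control_18S
}

#' Percent decline between genotypes with a two-tailed Welch t-test
#'
#' `100 * (mean_wt - mean_mut) / mean_wt`; positive values mean lower
#' signal in the mutant. Requires at least two replicates per genotype.
#'
#' @param values_wt,values_mut replicate-level normalized values.
#' @param alternative passed to the t-test; default two-sided.
#' @return list with `percent_decline`, `p_value`, `stderr_wt`,
#'   `stderr_mut`, `mean_wt`, `mean_mut`, `degenerate`.
#' @export
genotype_decline <- function(values_wt, values_mut,
                             alternative = "two.sided") {
  if (length(values_wt) < 2 || length(values_mut) < 2) {
    stop("need at least two replicates per genotype")
  }
  mw <- mean(values_wt)
  mm <- mean(values_mut)
  tt <- welch_test(values_mut, values_wt, alternative = alternative)
  list(
    percent_decline = if (mw != 0) 100 * (mw - mm) / mw else NA_real_,
    p_value = tt$p_value,
    stderr_wt = stats::sd(values_wt) / sqrt(length(values_wt)),
    stderr_mut = stats::sd(values_mut) / sqrt(length(values_mut)),
    mean_wt = mw, mean_mut = mm, degenerate = tt$degenerate
  )
}

#' Genotype comparison for a ChIP measurement table
#'
#' Expects a long table with columns `factor`, `gene_id`, `amplicon`,
#' `genotype`, `replicate`, `chip_signal`, `input_signal`,
#' `polII_chip_signal`, `polII_input_signal`. Occupancy is computed per
#' row, then compared between genotypes per (factor, gene, amplicon).
#'
#' @param table ChIP measurement data frame.
#' @param wt,mutant genotype labels.
#' @return data frame per (factor, gene_id, amplicon) with occupancy
#'   means, `percent_decline`, `p_value` and group standard errors.
#' @export
chip_decline_table <- function(table, wt = "WT", mutant = "mutant") {
  table$occupancy <- chip_occupancy(table$chip_signal, table$input_signal,
                                    table$polII_chip_signal,
                                    table$polII_input_signal,
                                    label = paste(table$factor, table$gene_id,
                                                  table$amplicon,
                                                  table$genotype,
                                                  table$replicate))
  keys <- unique(table[, c("factor", "gene_id", "amplicon")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    x <- table[table$factor == keys$factor[i] &
                 table$gene_id == keys$gene_id[i] &
                 table$amplicon == keys$amplicon[i], ]
    d <- genotype_decline(x$occupancy[x$genotype == wt],
                          x$occupancy[x$genotype == mutant])
    cbind(keys[i, , drop = FALSE],
          data.frame(mean_wt = d$mean_wt, mean_mut = d$mean_mut,
                     percent_decline = d$percent_decline,
                     p_value = d$p_value, stderr_wt = d$stderr_wt,
                     stderr_mut = d$stderr_mut))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Genotype comparison for a TRO measurement table
#'
#' Expects columns `gene_id`, `primer_id`, `genotype`, `replicate`,
#' `signal`, `control_18S`. The normalized signal is compared between
#' genotypes per (gene, primer).
#'
#' @param table TRO measurement data frame.
#' @param wt,mutant genotype labels.
#' @param alternative t-test sidedness, default two-sided.
#' @return data frame per (gene_id, primer_id) with normalized means,
#'   `percent_decline`, `p_value` and group standard errors.
#' @export
tro_decline_table <- function(table, wt = "WT", mutant = "mutant",
                              alternative = "two.sided") {
  table$norm <- tro_signal(table$signal, table$control_18S,
                           label = paste(table$gene_id, table$primer_id,
                                         table$genotype, table$replicate))
  keys <- unique(table[, c("gene_id", "primer_id")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    x <- table[table$gene_id == keys$gene_id[i] &
                 table$primer_id == keys$primer_id[i], ]
    d <- genotype_decline(x$norm[x$genotype == wt],
                          x$norm[x$genotype == mutant],
                          alternative = alternative)
    cbind(keys[i, , drop = FALSE],
          data.frame(mean_wt = d$mean_wt, mean_mut = d$mean_mut,
                     percent_decline = d$percent_decline,
                     p_value = d$p_value, stderr_wt = d$stderr_wt,
                     stderr_mut = d$stderr_mut))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
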