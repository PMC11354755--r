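#' Inclusion filters for the analyzed gene set
#'
#' Three criteria restrict the analysis to genes whose terminator region
#' can be assessed cleanly: (1) the 3' end must lie at least
#' `min_neighbor_distance_nt` from the next same-strand gene, because in a
#' compact genome the terminator of one gene often overlaps regulatory
#' regions of its neighbor; (2) the gene must be at least `min_length_nt`
#' long; (3) the gene must be transcriptionally active, with at least
#' `min_expression_reads_per_nt` within the CDS in at least
#' `min_replicates_passing` replicates (pooled over genotypes). All
#' thresholds are inclusive.
#'
#' @name gene_filtering
NULL

#' Filter configuration
#'
#' @param min_neighbor_distance_nt minimum 3'-end to neighbor distance (nt).
#' @param min_length_nt minimum gene length (nt).
#' @param min_expression_reads_per_nt minimum CDS read density (reads/nt).
#' @param min_replicates_passing replicates that must reach the expression
#'   threshold, counted across both genotypes.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_neighbor_distance_nt = 500,
                          min_length_nt = 500,
                          min_expression_reads_per_nt = 1.0,
                          min_replicates_passing = 3L) {
  stopifnot(min_neighbor_distance_nt >= 0, min_length_nt >= 0,
            min_expression_reads_per_nt >= 0, min_replicates_passing >= 0)
  structure(list(min_neighbor_distance_nt = min_neighbor_distance_nt,
                 min_length_nt = min_length_nt,
                 min_expression_reads_per_nt = min_expression_reads_per_nt,
                 min_replicates_passing = as.integer(min_replicates_passing)),
            class = "filter_config")
}

#' CDS read density of one gene in one replicate
#'
#' Strand-matched reads within the CDS divided by CDS length in
#' nucleotides.
#'
#' @param track a `coverage_track`.
#' @param gene one-row gene table entry.
#' @return reads per nucleotide (>= 0).
#' @export
expression_level <- function(track, gene) {
  if (isTRUE(gene$cds_missing) || is.na(gene$cds_start)) {
    stop("gene lacks CDS bounds: ", gene$gene_id)
  }
  len <- gene$cds_end - gene$cds_start
  if (len <= 0) stop("zero-length CDS: ", gene$gene_id)
  track_sum(track, gene$chrom, gene$strand, gene$cds_start, gene$cds_end) / len
}

#' Apply the three inclusion filters
#'
#' A gene passes iff its neighbor distance, length and expression all meet
#' the configured thresholds; the expression criterion must hold in at
#' least `min_replicates_passing` replicates pooled across genotypes. The
#' report records the funnel counts in filter order (distance, then
#' length, then expression); the final set is order-independent.
#'
#' @param genes gene table.
#' @param distances output of [neighbor_distances()].
#' @param tracks list of `coverage_track` objects (all replicates, both
#'   genotypes).
#' @param config a [filter_config()].
#' @return a `filter_report`: list with `per_gene` (pass/fail per
#'   criterion and per-replicate expression), `funnel` (counts surviving
#'   each successive filter) and `genes` (final gene ids).
#' @export
apply_filters <- function(genes, distances, tracks,
                          config = filter_config()) {
  if (nrow(genes) == 0L) stop("empty gene set")
  if (length(tracks) == 0L) stop("no coverage tracks supplied")
  m <- match(genes$gene_id, distances$gene_id)
  if (anyNA(m)) stop("neighbor distance missing for some genes")
  d <- distances$distance_nt[m]

  expr <- vapply(tracks, function(tr) {
    vapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      if (isTRUE(g$cds_missing)) return(NA_real_)
      expression_level(tr, g)
    }, numeric(1))
  }, numeric(nrow(genes)))
  expr <- matrix(expr, nrow = nrow(genes),
                 dimnames = list(genes$gene_id,
                                 vapply(tracks, `[[`, "", "sample_id")))
  n_pass <- rowSums(expr >= config$min_expression_reads_per_nt, na.rm = TRUE)

  per_gene <- data.frame(
    gene_id = genes$gene_id,
    neighbor_distance = d,
    pass_distance = d >= config$min_neighbor_distance_nt,
    length_nt = genes$length_nt,
    pass_length = genes$length_nt >= config$min_length_nt,
    replicates_passing = n_pass,
    pass_expression = n_pass >= config$min_replicates_passing,
    stringsAsFactors = FALSE
  )
  per_gene$pass_all <- per_gene$pass_distance & per_gene$pass_length &
    per_gene$pass_expression
  funnel <- c(
    input = nrow(genes),
    after_distance = sum(per_gene$pass_distance),
    after_length = sum(per_gene$pass_distance & per_gene$pass_length),
    after_expression = sum(per_gene$pass_all)
  )
  structure(list(per_gene = per_gene, funnel = funnel,
                 genes = per_gene$gene_id[per_gene$pass_all],
                 expression = expr, config = config),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:\n")
  f <- x$funnel
  cat(sprintf("  %-18s %d\n", names(f), f), sep = "")
  invisible(x)
}
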