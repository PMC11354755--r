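#' CDS-normalized metagene profiles and readthrough-ordered heat maps
#'
#' To compare genes of different expression levels on one axis, each
#' gene's per-nucleotide signal around the poly(A) site is divided by the
#' average read density in its CDS, so the gene-body plateau sits near 1
#' regardless of expression. The metagene profile averages these
#' normalized densities per offset over the pooled (gene x replicate)
#' values; the heat-map matrix keeps genes as rows, ordered by increasing
#' mutant readthrough so a termination defect appears as a growing
#' downstream block.
#'
#' @name metagene
NULL

#' Normalize a gene's windowed signal by its CDS mean density
#'
#' @param signal numeric vector from [extract_signal()].
#' @param cds_mean_density average read density in the CDS (> 0).
#' @return elementwise `signal / cds_mean_density`.
#' @export
normalize_gene <- function(signal, cds_mean_density) {
  if (!is.finite(cds_mean_density) || cds_mean_density <= 0) {
    stop("cds_mean_density must be > 0; gene must be excluded upstream")
  }
  signal / cds_mean_density
}

## Normalized window rows for every (gene, replicate) with a full window
## and positive CDS density; returns matrix rows + bookkeeping.
metagene_rows <- function(tracks, genes, window) {
  width <- window[2] - window[1]
  rows <- list()
  meta <- list()
  for (tr in tracks) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      sig <- extract_signal(tr, g, window)
      if (attr(sig, "truncated")) next
      dens <- expression_level(tr, g)
      if (dens <= 0) next
      rows[[length(rows) + 1L]] <- normalize_gene(as.numeric(sig), dens)
      meta[[length(meta) + 1L]] <- c(g$gene_id, tr$sample_id)
    }
  }
  if (!length(rows)) stop("no (gene, replicate) pair with a full window")
  mat <- do.call(rbind, rows)
  info <- do.call(rbind, meta)
  list(matrix = mat,
       gene_id = info[, 1], sample_id = info[, 2], width = width)
}

#' Metagene profile around the poly(A) site for one genotype
#'
#' @param tracks list of `coverage_track` objects (replicates of one
#'   genotype).
#' @param genes gene table (the analyzed set).
#' @param window strandward offset window, default `c(-200, 200)` giving
#'   offsets -200..+199.
#' @return list with `profile` (data frame: `offset`, `mean`, `stderr`),
#'   `n_genes` and `n_rows` (pooled gene x replicate count).
#' @export
metagene_profile <- function(tracks, genes, window = c(-200, 200)) {
  mg <- metagene_rows(tracks, genes, window)
  n <- nrow(mg$matrix)
  mu <- colMeans(mg$matrix)
  se <- if (n > 1) apply(mg$matrix, 2, stats::sd) / sqrt(n) else
    rep(0, ncol(mg$matrix))
  list(profile = data.frame(offset = window[1]:(window[2] - 1), mean = mu,
                            stderr = se),
       n_genes = length(unique(mg$gene_id)), n_rows = n)
}

#' Readthrough-ordered heat-map matrices, one per sample
#'
#' Rows are genes ordered by ascending per-gene mean mutant RTI (ties
#' broken by gene id; genes without a defined mutant RTI are placed last
#' and flagged); the order is identical across all samples of both
#' genotypes. Cells are CDS-normalized densities over the offset window.
#'
#' @param tracks list of `coverage_track` objects (all samples).
#' @param genes gene table.
#' @param rti data frame from [rti_table()] used for ordering.
#' @param mutant genotype label whose RTI orders the rows.
#' @param window strandward offset window, default `c(-200, 200)`.
#' @return list with `matrices` (named list of gene x offset matrices per
#'   sample) and `order` (data frame: `gene_id`, `order_key`,
#'   `missing_rti`).
#' @export
heatmap_matrix <- function(tracks, genes, rti, mutant = "mutant",
                           window = c(-200, 200)) {
  ok <- rti$complete & !is.na(rti$rti) & rti$genotype == mutant
  key <- stats::aggregate(rti ~ gene_id, data = rti[ok, , drop = FALSE],
                          FUN = mean)
  m <- match(genes$gene_id, key$gene_id)
  ord_df <- data.frame(gene_id = genes$gene_id, order_key = key$rti[m],
                       missing_rti = is.na(m), stringsAsFactors = FALSE)
  ord <- order(ord_df$missing_rti, ord_df$order_key, ord_df$gene_id)
  ord_df <- ord_df[ord, ]
  offs <- window[1]:(window[2] - 1)
  mats <- lapply(tracks, function(tr) {
    mat <- matrix(NA_real_, nrow = nrow(ord_df), ncol = length(offs),
                  dimnames = list(ord_df$gene_id, offs))
    for (gid in ord_df$gene_id) {
      g <- genes[genes$gene_id == gid, ]
      sig <- extract_signal(tr, g, window)
      if (attr(sig, "truncated")) next
      dens <- expression_level(tr, g)
      if (dens <= 0) next
      mat[gid, ] <- normalize_gene(as.numeric(sig), dens)
    }
    mat
  })
  names(mats) <- vapply(tracks, `[[`, "", "sample_id")
  list(matrices = mats, order = ord_df)
}

#' Plot metagene profiles with standard-error bands
#'
#' @param profiles named list of [metagene_profile()] results, one per
#'   genotype.
#' @param path optional output file; when given the plot is saved there.
#' @return the ggplot object, invisibly.
#' @export
plot_metagene <- function(profiles, path = NULL) {
  df <- do.call(rbind, lapply(names(profiles), function(gt) {
    cbind(profiles[[gt]]$profile, genotype = gt)
  }))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$offset, y = .data$mean,
                                        color = .data$genotype,
                                        fill = .data$genotype)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$stderr,
                                      ymax = .data$mean + .data$stderr),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "distance from poly(A) site (nt)",
                  y = "CDS-normalized read density") +
    ggplot2::theme_classic()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 6, height = 4)
  invisible(p)
}

#' Render one heat-map matrix to a file
#'
#' @param mat gene x offset matrix from [heatmap_matrix()].
#' @param path output image path (e.g. PNG).
#' @param cap densities above this value are truncated for display.
#' @return `path`, invisibly.
#' @export
plot_heatmap <- function(mat, path, cap = 2) {
  mat <- pmin(mat, cap)
  mat[is.na(mat)] <- 0
  pheatmap::pheatmap(mat, cluster_rows = FALSE, cluster_cols = FALSE,
                     show_rownames = FALSE, show_colnames = FALSE,
                     color = grDevices::colorRampPalette(c("black", "red"))(100),
                     filename = path)
  invisible(path)
}
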