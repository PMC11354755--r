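#' Gene annotation input and 3'-end geometry
#'
#' All coordinates inside the package follow one convention: 0-based,
#' half-open `[start, end)`, as in BED. GFF3 input (1-based, closed) is
#' converted on read. The poly(A) site is the 0-based coordinate of the
#' last transcribed nucleotide of the gene: `end - 1` on the plus strand,
#' `start` on the minus strand, unless an override table supplies an
#' annotated cleavage site.
#'
#' @name annotation
NULL

#' Load a gene annotation as a gene table
#'
#' Reads protein-coding gene models from GFF3 or BED6 and returns one row
#' per gene in the internal 0-based half-open convention. For GFF3, rows of
#' type `gene` define the gene span and rows of type `CDS` (matched through
#' their `Parent` or `ID` attribute) define the CDS bounds; a gene without
#' CDS rows gets `NA` CDS bounds, is flagged, and a count of such genes is
#' messaged. BED6 carries no CDS information, so CDS bounds default to the
#' full gene span unless `bed_cds = "missing"`.
#'
#' @param path annotation file path.
#' @param format `"gff3"` or `"bed"`.
#' @param polya_override optional path to a TSV
#'   (`gene_id<TAB>chrom<TAB>coord<TAB>strand`, 0-based coordinate of the
#'   last transcribed nucleotide) overriding the default poly(A) site.
#' @param bed_cds for BED input: `"span"` (default) uses the gene span as
#'   CDS, `"missing"` leaves CDS bounds `NA`.
#' @return a `gene_table` data frame with columns `gene_id`, `chrom`,
#'   `strand`, `start`, `end`, `polyA_site`, `cds_start`, `cds_end`,
#'   `length_nt` and a logical `cds_missing` flag.
#' @export
load_annotation <- function(path, format = c("gff3", "bed"),
                            polya_override = NULL,
                            bed_cds = c("span", "missing")) {
  format <- match.arg(format)
  bed_cds <- match.arg(bed_cds)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    genes <- gr[tolower(as.character(gr$type)) == "gene"]
    if (length(genes) == 0L) stop("no 'gene' features in GFF3: ", path)
    ids <- genes$ID
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene feature lacks ID attribute")
    cds <- gr[tolower(as.character(gr$type)) == "cds"]
    cds_parent <- if (length(cds)) {
      p <- as.character(vapply(as.list(cds$Parent %||% cds$ID),
                               function(x) if (length(x)) x[[1]] else NA_character_,
                               character(1)))
      ifelse(is.na(p) & !is.null(cds$ID), cds$ID, p)
    } else character(0)
    cds_start <- cds_end <- rep(NA_real_, length(genes))
    for (i in seq_along(genes)) {
      hit <- which(cds_parent == ids[i])
      if (length(hit)) {
        cds_start[i] <- min(GenomicRanges::start(cds[hit])) - 1L
        cds_end[i] <- max(GenomicRanges::end(cds[hit]))
      }
    }
    tab <- data.frame(
      gene_id = ids,
      chrom = as.character(GenomicRanges::seqnames(genes)),
      strand = as.character(GenomicRanges::strand(genes)),
      start = GenomicRanges::start(genes) - 1L,  # 1-based closed -> 0-based half-open
      end = GenomicRanges::end(genes),
      cds_start = cds_start,
      cds_end = cds_end,
      stringsAsFactors = FALSE
    )
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stop("no records in BED: ", path)
    nm <- gr$name %||% paste0("gene", seq_along(gr))
    tab <- data.frame(
      gene_id = nm,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE
    )
    if (bed_cds == "span") {
      tab$cds_start <- tab$start
      tab$cds_end <- tab$end
    } else {
      tab$cds_start <- NA_real_
      tab$cds_end <- NA_real_
    }
  }
  if (any(!tab$strand %in% c("+", "-"))) {
    stop("strandless gene records: ",
         paste(tab$gene_id[!tab$strand %in% c("+", "-")], collapse = ", "))
  }
  tab$polyA_site <- ifelse(tab$strand == "+", tab$end - 1, tab$start)
  if (!is.null(polya_override)) {
    ov <- utils::read.table(polya_override, sep = "\t", header = FALSE,
                            col.names = c("gene_id", "chrom", "coord", "strand"),
                            stringsAsFactors = FALSE)
    m <- match(tab$gene_id, ov$gene_id)
    hit <- !is.na(m)
    tab$polyA_site[hit] <- ov$coord[m[hit]]
  }
  tab$length_nt <- tab$end - tab$start
  tab$cds_missing <- is.na(tab$cds_start)
  if (any(tab$cds_missing)) {
    message(sum(tab$cds_missing),
            " gene(s) lack CDS annotation; excluded from CDS-dependent steps")
  }
  tab <- tab[, c("gene_id", "chrom", "strand", "start", "end", "polyA_site",
                 "cds_start", "cds_end", "length_nt", "cds_missing")]
  validate_gene_table(tab)
  class(tab) <- c("gene_table", "data.frame")
  tab
}

#' Check gene-table invariants
#'
#' @param tab gene table data frame.
#' @return `tab`, invisibly; errors on the first violated invariant.
#' @export
validate_gene_table <- function(tab) {
  stopifnot(is.data.frame(tab))
  if (any(tab$start >= tab$end)) stop("gene with start >= end")
  if (any(tab$length_nt < 1)) stop("gene with length < 1 nt")
  ok <- tab$cds_missing | (tab$cds_start >= tab$start & tab$cds_end <= tab$end &
                             tab$cds_start < tab$cds_end)
  if (any(!ok, na.rm = TRUE)) {
    stop("CDS bounds not nested in gene span: ",
         paste(tab$gene_id[!ok], collapse = ", "))
  }
  if (anyDuplicated(tab$gene_id)) stop("duplicated gene_id")
  invisible(tab)
}

#' Distance from each gene's 3' end to its nearest same-strand downstream gene
#'
#' Downstream means 3' of the poly(A) site in the direction of
#' transcription: increasing coordinates on the plus strand, decreasing on
#' the minus strand. The distance is the number of nucleotides separating
#' the 3'-end nucleotide from the nearest nucleotide of the downstream
#' gene (nearest edge). A gene overlapping the 3' end gives distance 0; a
#' gene with no same-strand downstream neighbor gets `Inf`, which passes
#' any threshold.
#'
#' @param genes gene table from [load_annotation()].
#' @return data frame with `gene_id` and `distance_nt`.
#' @export
neighbor_distances <- function(genes) {
  n <- nrow(genes)
  dist <- rep(Inf, n)
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i] &
                    genes$strand == genes$strand[i] &
                    seq_len(n) != i)
    if (!length(same)) next
    pa <- genes$polyA_site[i]
    if (genes$strand[i] == "+") {
      cand <- same[genes$end[same] > pa + 1]       # has a nucleotide 3' of pa
      if (length(cand)) dist[i] <- min(pmax(0, genes$start[cand] - pa - 1))
    } else {
      cand <- same[genes$start[same] < pa]         # has a nucleotide 3' of pa
      if (length(cand)) dist[i] <- min(pmax(0, pa - genes$end[cand]))
    }
  }
  data.frame(gene_id = genes$gene_id, distance_nt = dist,
             stringsAsFactors = FALSE)
}

#' Write gene models as BED6
#'
#' @param genes gene table.
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_annotation_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$name <- genes$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write the canonical gene table (with neighbor distances) as TSV
#'
#' @param genes gene table.
#' @param distances output of [neighbor_distances()].
#' @param path output path.
#' @param params parameter header entries, see [write_tsv_header()].
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, distances, path, params = list()) {
  m <- match(genes$gene_id, distances$gene_id)
  out <- data.frame(genes[, c("gene_id", "chrom", "strand", "start", "end",
                              "polyA_site", "cds_start", "cds_end")],
                    neighbor_distance = distances$distance_nt[m])
  write_tsv_header(out, path, params)
}
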