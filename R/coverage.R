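#' Strand-specific per-nucleotide coverage tracks
#'
#' A `coverage_track` stores, for one sequencing replicate, dense
#' per-nucleotide read counts for both strands of every chromosome. The
#' count at 0-based genomic position `p` of chromosome `chr` on strand `s`
#' lives at `track$cov[[chr]][[s]][p + 1]`. Counts are read 3' ends, so a
#' position holds the number of nascent-RNA 3' termini mapped there.
#'
#' @name coverage
NULL

new_coverage_track <- function(sample_id, genotype, replicate, chrom_sizes,
                               cov) {
  structure(list(sample_id = sample_id, genotype = genotype,
                 replicate = as.integer(replicate),
                 chrom_sizes = chrom_sizes, cov = cov),
            class = "coverage_track")
}

#' Construct a coverage track from in-memory vectors
#'
#' @param cov named list: per chromosome, a list with elements `"+"` and
#'   `"-"`, each a numeric vector of per-nucleotide counts (index `p + 1`
#'   holds 0-based position `p`).
#' @param sample_id,genotype,replicate sample metadata.
#' @return a `coverage_track`.
#' @export
coverage_track <- function(cov, sample_id = "sample", genotype = "WT",
                           replicate = 1L) {
  stopifnot(is.list(cov), length(cov) > 0, !is.null(names(cov)))
  chrom_sizes <- vapply(names(cov), function(ch) {
    x <- cov[[ch]]
    if (!all(c("+", "-") %in% names(x))) {
      stop("both strands required for chromosome ", ch)
    }
    if (length(x[["+"]]) != length(x[["-"]])) {
      stop("strand arrays differ in length on ", ch)
    }
    if (any(x[["+"]] < 0) || any(x[["-"]] < 0)) {
      stop("negative counts on ", ch)
    }
    length(x[["+"]])
  }, numeric(1))
  new_coverage_track(sample_id, genotype, replicate, chrom_sizes, cov)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track", x$sample_id, sprintf("(%s, rep %d)\n", x$genotype,
                                             x$replicate))
  cat(" chromosomes:", paste(names(x$chrom_sizes), collapse = ", "), "\n")
  cat(" total reads:", total_reads(x), "\n")
  invisible(x)
}

#' Read a two-column chrom.sizes table
#' @param path TSV with chromosome name and length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}

bedgraph_to_dense <- function(path, chrom_sizes) {
  dense <- lapply(chrom_sizes, function(L) numeric(L))
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(dense)
  chr <- as.character(GenomicRanges::seqnames(gr))
  bad <- !chr %in% names(chrom_sizes)
  if (any(bad)) stop("bedGraph chromosome not in chrom.sizes: ",
                     paste(unique(chr[bad]), collapse = ", "))
  over <- GenomicRanges::end(gr) > chrom_sizes[chr]
  if (any(over)) stop("bedGraph interval beyond chromosome end on ",
                      paste(unique(chr[over]), collapse = ", "))
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  for (ch in names(chrom_sizes)) dense[[ch]] <- as.numeric(cov[[ch]])
  dense
}

#' Load strand-specific coverage for one replicate
#'
#' The primary ingestion format is a bedGraph pair (one file per strand,
#' 4-column, 0-based half-open). Alternatively a coordinate-sorted,
#' indexed BAM of 3'-end reads can be given, in which case each read
#' contributes one count at its 3'-most aligned position on its own
#' strand.
#'
#' @param plus_path,minus_path bedGraph paths for the plus and minus
#'   strand (ignored when `bam` is given).
#' @param chrom_sizes named chromosome lengths, see [read_chrom_sizes()].
#' @param sample_id sample label.
#' @param genotype genotype label, e.g. `"WT"` or `"mutant"`.
#' @param replicate replicate number (>= 1).
#' @param bam optional BAM path used instead of the bedGraph pair.
#' @return a `coverage_track`.
#' @export
load_coverage <- function(plus_path = NULL, minus_path = NULL, chrom_sizes,
                          sample_id = "sample", genotype = "WT",
                          replicate = 1L, bam = NULL) {
  stopifnot(length(chrom_sizes) > 0, all(chrom_sizes > 0))
  if (!is.null(bam)) {
    aln <- GenomicAlignments::readGAlignments(bam)
    chr <- as.character(GenomicAlignments::seqnames(aln))
    bad <- !chr %in% names(chrom_sizes)
    if (any(bad)) stop("BAM chromosome not in chrom.sizes: ",
                       paste(unique(chr[bad]), collapse = ", "))
    str <- as.character(GenomicAlignments::strand(aln))
    # 3'-most aligned base: rightmost on +, leftmost on - (1-based index
    # into the dense array equals 0-based position + 1)
    idx <- ifelse(str == "+", GenomicAlignments::end(aln),
                  GenomicAlignments::start(aln))
    cov <- lapply(chrom_sizes, function(L) {
      list(`+` = numeric(L), `-` = numeric(L))
    })
    for (s in c("+", "-")) {
      sel <- str == s
      if (!any(sel)) next
      tab <- table(paste(chr[sel], idx[sel]))
      parts <- strsplit(names(tab), " ", fixed = TRUE)
      for (k in seq_along(tab)) {
        cov[[parts[[k]][1]]][[s]][as.integer(parts[[k]][2])] <-
          as.numeric(tab[k])
      }
    }
  } else {
    if (is.null(plus_path) || is.null(minus_path)) {
      stop("both plus_path and minus_path are required (or a BAM)")
    }
    for (p in c(plus_path, minus_path)) {
      if (!file.exists(p)) stop("coverage file missing: ", p)
    }
    plus <- bedgraph_to_dense(plus_path, chrom_sizes)
    minus <- bedgraph_to_dense(minus_path, chrom_sizes)
    cov <- lapply(names(chrom_sizes), function(chr) {
      list(`+` = plus[[chr]], `-` = minus[[chr]])
    })
    names(cov) <- names(chrom_sizes)
  }
  new_coverage_track(sample_id, genotype, replicate, chrom_sizes, cov)
}

#' Read a sample sheet and load all replicate tracks
#'
#' The sheet is a TSV with columns `sample_id`, `genotype`, `replicate`,
#' `plus_path`, `minus_path`; relative paths are resolved against the
#' sheet's directory.
#'
#' @param path sample sheet path.
#' @param chrom_sizes named chromosome lengths.
#' @return list of `coverage_track` objects, one per row.
#' @export
load_samples <- function(path, chrom_sizes) {
  sheet <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  need <- c("sample_id", "genotype", "replicate", "plus_path", "minus_path")
  if (!all(need %in% names(sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  resolve <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  lapply(seq_len(nrow(sheet)), function(i) {
    load_coverage(resolve(sheet$plus_path[i]), resolve(sheet$minus_path[i]),
                  chrom_sizes, sample_id = sheet$sample_id[i],
                  genotype = sheet$genotype[i],
                  replicate = sheet$replicate[i])
  })
}

## Sum of strand-matched counts over a 0-based half-open interval.
track_sum <- function(track, chrom, strand, start, end) {
  arr <- track$cov[[chrom]][[strand]]
  if (is.null(arr)) stop("chromosome absent from track: ", chrom)
  start <- max(start, 0)
  end <- min(end, length(arr))
  if (start >= end) return(0)
  sum(arr[(start + 1):end])
}

#' Total read count of a coverage track (both strands)
#' @param track a `coverage_track`.
#' @return numeric total.
#' @export
total_reads <- function(track) {
  sum(vapply(track$cov, function(ch) sum(ch[["+"]]) + sum(ch[["-"]]),
             numeric(1)))
}

#' Multiply all counts of a track by a constant
#'
#' Used to check scale invariance of ratio statistics.
#' @param track a `coverage_track`.
#' @param k positive factor.
#' @return scaled `coverage_track`.
#' @export
scale_coverage <- function(track, k) {
  stopifnot(k > 0)
  track$cov <- lapply(track$cov, function(ch) lapply(ch, function(a) a * k))
  track
}

#' Extract a strand-oriented signal vector for one gene
#'
#' Returns counts over a window of strandward offsets relative to an
#' anchor, oriented 5' to 3' along the gene's strand: index 1 is the most
#' 5' requested offset, negative offsets are upstream in the sense of
#' transcription. Offsets follow the half-open convention
#' `[window[1], window[2])`; offset 0 is the anchor nucleotide itself.
#' Positions falling off the chromosome are returned as `NA` and the
#' result carries `attr(, "truncated") = TRUE`; callers that require full
#' windows exclude such genes.
#'
#' @param track a `coverage_track`.
#' @param gene one-row gene table entry (or list with `chrom`, `strand`,
#'   `polyA_site`, `cds_start`, `cds_end`).
#' @param window integer pair of half-open strandward offsets.
#' @param anchor `"polyA_site"` (default) or `"cds_start"` (the strand-aware
#'   first CDS nucleotide).
#' @return numeric vector of length `window[2] - window[1]` with attribute
#'   `truncated`.
#' @export
extract_signal <- function(track, gene, window, anchor = c("polyA_site",
                                                           "cds_start")) {
  anchor <- match.arg(anchor)
  stopifnot(length(window) == 2, window[1] < window[2])
  a <- if (anchor == "polyA_site") gene$polyA_site else {
    if (gene$strand == "+") gene$cds_start else gene$cds_end - 1
  }
  offs <- window[1]:(window[2] - 1)
  pos <- if (gene$strand == "+") a + offs else a - offs  # 0-based genomic
  arr <- track$cov[[gene$chrom]][[gene$strand]]
  if (is.null(arr)) stop("chromosome absent from track: ", gene$chrom)
  inside <- pos >= 0 & pos < length(arr)
  values <- rep(NA_real_, length(pos))
  values[inside] <- arr[pos[inside] + 1]
  attr(values, "truncated") <- any(!inside)
  values
}
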