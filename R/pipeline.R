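#' End-to-end pipeline orchestration
#'
#' `run_pipeline()` chains the analysis stages — gene filtering,
#' per-replicate readthrough index, differential readthrough calling,
#' metagene profiles and the readthrough-ordered heat-map matrices — in
#' dependency order, writing every table as TSV with a commented
#' parameter header so any printed number is auditable. A stage requested
#' without its upstream stage (in the same run or as an artifact from a
#' previous run) raises an error naming the stage to run first.
#'
#' @name cli_pipeline
NULL

#' Pipeline run configuration
#'
#' @param annotation annotation path.
#' @param format annotation format, `"gff3"` or `"bed"`.
#' @param sample_sheet sample sheet TSV path (see [load_samples()]).
#' @param chrom_sizes chrom.sizes path.
#' @param outdir output directory.
#' @param filter a [filter_config()].
#' @param exclusion_nt,window_nt RTI window geometry.
#' @param alpha,log2_fc_threshold,min_total,min_per_group differential
#'   calling parameters.
#' @param metagene_window strandward offset window for profiles.
#' @param wt,mutant genotype labels as used in the sample sheet.
#' @param polya_override optional poly(A)-site override TSV.
#' @return a `run_config` list.
#' @export
run_config <- function(annotation, sample_sheet, chrom_sizes, outdir,
                       format = "gff3", filter = filter_config(),
                       exclusion_nt = 50, window_nt = 450, alpha = 0.05,
                       log2_fc_threshold = 1.0, min_total = 5L,
                       min_per_group = 2L, metagene_window = c(-200, 200),
                       wt = "WT", mutant = "mutant", polya_override = NULL) {
  for (p in c(annotation, sample_sheet, chrom_sizes)) {
    if (!file.exists(p)) stop("input file missing: ", p)
  }
  structure(list(annotation = annotation, sample_sheet = sample_sheet,
                 chrom_sizes = chrom_sizes, outdir = outdir, format = format,
                 filter = filter, exclusion_nt = exclusion_nt,
                 window_nt = window_nt, alpha = alpha,
                 log2_fc_threshold = log2_fc_threshold,
                 min_total = as.integer(min_total),
                 min_per_group = as.integer(min_per_group),
                 metagene_window = metagene_window, wt = wt, mutant = mutant,
                 polya_override = polya_override),
            class = "run_config")
}

#' Run the analysis pipeline
#'
#' @param config a [run_config()].
#' @param stages subset of `c("filter", "rti", "diff", "metagene",
#'   "heatmap")`; stages run in dependency order.
#' @return list with `status` (0 on success), `manifest` (named vector of
#'   written files) and the in-memory stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("filter", "rti", "diff", "metagene",
                                    "heatmap")) {
  stages <- match.arg(stages, several.ok = TRUE)
  deps <- list(filter = character(0), rti = "filter", diff = "rti",
               metagene = "filter", heatmap = "rti")
  order_all <- c("filter", "rti", "diff", "metagene", "heatmap")
  stages <- order_all[order_all %in% stages]
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  res <- list()
  params <- list(
    min_neighbor_distance_nt = config$filter$min_neighbor_distance_nt,
    min_length_nt = config$filter$min_length_nt,
    min_expression_reads_per_nt = config$filter$min_expression_reads_per_nt,
    min_replicates_passing = config$filter$min_replicates_passing,
    exclusion_nt = config$exclusion_nt, window_nt = config$window_nt,
    alpha = config$alpha, log2_fc_threshold = config$log2_fc_threshold,
    min_total = config$min_total, min_per_group = config$min_per_group,
    metagene_window = config$metagene_window
  )
  out <- function(name) file.path(config$outdir, name)
  require_stage <- function(stage, artifact) {
    need <- deps[[stage]]
    for (d in need) {
      if (!d %in% stages && !file.exists(out(artifact))) {
        stop("stage '", stage, "' requires stage '", d,
             "' to be run first (missing artifact ", artifact, ")")
      }
    }
  }

  chrom_sizes <- read_chrom_sizes(config$chrom_sizes)
  genes <- load_annotation(config$annotation, format = config$format,
                           polya_override = config$polya_override)
  distances <- neighbor_distances(genes)
  tracks <- load_samples(config$sample_sheet, chrom_sizes)
  message("loaded ", nrow(genes), " genes, ", length(tracks), " tracks")

  if ("filter" %in% stages) {
    res$filter <- apply_filters(genes, distances, tracks, config$filter)
    f <- res$filter$funnel
    message("filter funnel: ", paste(names(f), f, sep = "=", collapse = " "))
    manifest["gene_table"] <- write_gene_table(genes, distances,
                                               out("gene_table.tsv"), params)
    manifest["filter_funnel"] <- write_tsv_header(
      data.frame(step = names(f), genes = unname(f)),
      out("filter_funnel.tsv"), params)
    manifest["gene_list"] <- write_tsv_header(
      data.frame(gene_id = res$filter$genes), out("gene_list.tsv"), params)
  }

  analyzed <- function() {
    if (!is.null(res$filter)) {
      genes[genes$gene_id %in% res$filter$genes, , drop = FALSE]
    } else {
      ids <- read_tsv_header(out("gene_list.tsv"))$gene_id
      genes[genes$gene_id %in% ids, , drop = FALSE]
    }
  }

  if ("rti" %in% stages) {
    require_stage("rti", "gene_list.tsv")
    res$rti <- rti_table(tracks, analyzed(), config$exclusion_nt,
                         config$window_nt)
    manifest["rti"] <- write_tsv_header(res$rti, out("rti.tsv"), params)
    message("rti: ", length(unique(res$rti$gene_id)), " genes x ",
            length(tracks), " samples")
  }

  get_rti <- function(stage) {
    if (!is.null(res$rti)) return(res$rti)
    require_stage(stage, "rti.tsv")
    read_tsv_header(out("rti.tsv"))
  }

  if ("diff" %in% stages) {
    rt <- get_rti("diff")
    res$diff <- differential_readthrough(
      rt, wt = config$wt, mutant = config$mutant, alpha = config$alpha,
      log2_fc_threshold = config$log2_fc_threshold,
      min_total = config$min_total, min_per_group = config$min_per_group)
    manifest["differential"] <- write_tsv_header(res$diff,
                                                 out("differential.tsv"),
                                                 params)
    manifest["volcano"] <- write_tsv_header(volcano_data(res$diff),
                                            out("volcano.tsv"), params)
    res$summary <- summarize_rti(res$diff, rt, wt = config$wt,
                                 mutant = config$mutant)
    jsonlite::write_json(c(res$summary, params), out("summary.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest["summary"] <- out("summary.json")
    message(sprintf("differential: %.1f%% of %d genes significant",
                    100 * res$summary$fraction_significant,
                    res$summary$n_genes))
  }

  if ("metagene" %in% stages) {
    require_stage("metagene", "gene_list.tsv")
    ga <- analyzed()
    for (gt in c(config$wt, config$mutant)) {
      trs <- Filter(function(t) t$genotype == gt, tracks)
      prof <- metagene_profile(trs, ga, config$metagene_window)
      res$metagene[[gt]] <- prof
      manifest[paste0("metagene_", gt)] <- write_tsv_header(
        prof$profile, out(sprintf("metagene_%s.tsv", gt)),
        c(params, list(genotype = gt, n_genes = prof$n_genes)))
    }
  }

  if ("heatmap" %in% stages) {
    rt <- get_rti("heatmap")
    res$heatmap <- heatmap_matrix(tracks, analyzed(), rt,
                                  mutant = config$mutant,
                                  window = config$metagene_window)
    for (s in names(res$heatmap$matrices)) {
      mat <- res$heatmap$matrices[[s]]
      manifest[paste0("heatmap_", s)] <- write_tsv_header(
        data.frame(gene_id = rownames(mat), mat, check.names = FALSE),
        out(sprintf("heatmap_%s.tsv", s)), c(params, list(sample = s)))
    }
  }

  list(status = 0L, manifest = manifest, results = res)
}
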