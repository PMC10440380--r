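## End-to-end orchestration: normalize -> DE (1 wk, 40 wk) -> overlap ->
## interaction -> cluster/summarize -> markers -> assignment -> enrichment,
## writing every stage's table plus a run manifest.

#' Build a pipeline configuration
#'
#' Collects file paths, thresholds and flags for [run_pipeline()]. Every
#' threshold defaults to the analysis's headline value: DE fold-change
#' gates 2 and 0.5 at FDR 0.1, marker gate at normalized UMI 1.0, k = 8
#' expression clusters. The preset `interaction_strict` tightens the
#' interaction FDR to 0.01 (the cutoff used for the merged early/late gene
#' set).
#'
#' @param counts,design Paths to the bulk counts TSV and design TSV (or
#'   in-memory matrix/data.frame).
#' @param outdir Output directory.
#' @param sc_counts Optional single-cell MTX path (with `genes.tsv` /
#'   `barcodes.tsv` sidecars) or gene x cell matrix.
#' @param sc_labels Optional cell-label TSV (`cell_id`, `cell_type`) or
#'   named vector; when absent and `sc_counts` is given, cells are
#'   clustered with [cluster_cells()].
#' @param gmt Optional GMT path or named list of gene sets.
#' @param fc_up,fc_down,fdr_max DE gates (defaults 2, 0.5, 0.1).
#' @param interaction_fdr Interaction screen FDR for downstream selection
#'   (default 0.1; 0.01 under the `interaction_strict` preset).
#' @param umi_min,min_log2fc,q_max Marker-derivation gates (defaults 1.0,
#'   1.0, 0.05).
#' @param k Number of expression clusters (default 8).
#' @param seed Integer seed for clustering and GSEA permutations.
#' @param standardize Row-standardize before k-means (default TRUE).
#' @param unique_markers Enforce marker uniqueness (default TRUE).
#' @param denominator Assignment-summary denominator (default "queried").
#' @param by_sex Stratify the DE screens by sex (default FALSE pools
#'   sexes).
#' @param preset `"default"` or `"interaction_strict"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts, design, outdir, sc_counts = NULL,
                            sc_labels = NULL, gmt = NULL, fc_up = 2,
                            fc_down = 0.5, fdr_max = 0.1,
                            interaction_fdr = 0.1, umi_min = 1,
                            min_log2fc = 1, q_max = 0.05, k = 8, seed = 1,
                            standardize = TRUE, unique_markers = TRUE,
                            denominator = "queried", by_sex = FALSE,
                            preset = c("default", "interaction_strict")) {
  preset <- match.arg(preset)
  if (preset == "interaction_strict") interaction_fdr <- 0.01
  stopifnot(fc_up > 1, fc_down < 1, fdr_max > 0, fdr_max <= 1,
            interaction_fdr > 0, interaction_fdr <= 1, umi_min >= 0,
            q_max > 0, q_max <= 1)
  if (!is_count(k)) stopf("k must be a positive integer")
  structure(list(counts = counts, design = design, outdir = outdir,
                 sc_counts = sc_counts, sc_labels = sc_labels, gmt = gmt,
                 fc_up = fc_up, fc_down = fc_down, fdr_max = fdr_max,
                 interaction_fdr = interaction_fdr, umi_min = umi_min,
                 min_log2fc = min_log2fc, q_max = q_max, k = k,
                 seed = as.integer(seed), standardize = standardize,
                 unique_markers = unique_markers, denominator = denominator,
                 by_sex = by_sex, preset = preset),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [pipeline_config()]; reading a
#' written config reproduces an identical object.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Save a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

resolve_counts <- function(x, ...) if (is.character(x)) read_counts(x, ...) else x
resolve_design <- function(x) {
  if (is.character(x)) read_design(x) else validate_design(x)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: quantile normalization, log2 transform, WD/LFD
#' differential expression at 1 and 40 weeks, overlap bookkeeping, the
#' diet x time interaction screen, progressive-gene selection, per-group
#' geometric means, k-means clustering with cluster summaries, and — when
#' single-cell inputs are configured — marker derivation and bulk-to-cell-
#' type assignment, plus ORA/GSEA when a gene-set collection is configured.
#' Every stage writes a TSV under `outdir`; a `run_manifest.yaml` records
#' the config echo, seed, package version and per-stage row counts.
#' Identical config + inputs reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage result and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- resolve_counts(cfg$counts)
  design <- resolve_design(cfg$design)
  miss <- setdiff(design$sample_id, colnames(counts))
  if (length(miss))
    stopf("design sample(s) absent from counts: %s", paste(miss, collapse = ", "))

  stages <- list(); manifest <- list()
  note <- function(name, n) manifest[[name]] <<- n

  norm <- quantile_normalize(counts[, design$sample_id, drop = FALSE])
  lg <- log2_transform(norm)
  note("normalize", nrow(norm))

  de1 <- de_per_timepoint(lg, design, 1, cfg$fc_up, cfg$fc_down, cfg$fdr_max,
                          by_sex = cfg$by_sex)
  de40 <- de_per_timepoint(lg, design, 40, cfg$fc_up, cfg$fc_down, cfg$fdr_max,
                           by_sex = cfg$by_sex)
  if (cfg$by_sex) { de1 <- de1$F; de40 <- de40$F }  # stratified: report F; M written too
  write_tsv(de1, file.path(cfg$outdir, "de_1wk.tsv"))
  write_tsv(de40, file.path(cfg$outdir, "de_40wk.tsv"))
  note("de_1wk", sum(de1$call != "ns")); note("de_40wk", sum(de40$call != "ns"))

  ov <- overlap_sets(de1, de40)
  write_tsv(data.frame(metric = names(ov)[1:10],
                       value = unlist(ov[1:10], use.names = FALSE)),
            file.path(cfg$outdir, "overlap.tsv"))
  writeLines(ov$common_genes, file.path(cfg$outdir, "common_genes.txt"))
  note("overlap", ov$n_common)

  itab <- interaction_test(lg, design)
  write_tsv(itab, file.path(cfg$outdir, "interaction.tsv"))
  int_genes <- itab$gene_id[!is.na(itab$q_value) &
                              itab$q_value <= cfg$interaction_fdr]
  note("interaction", length(int_genes))
  progressive <- select_progressive_genes(itab, q_max = cfg$interaction_fdr)
  writeLines(progressive, file.path(cfg$outdir, "progressive_genes.txt"))
  note("progressive", length(progressive))

  gm <- group_geometric_means(norm, design)
  write_tsv(data.frame(gene_id = rownames(gm), gm, check.names = FALSE),
            file.path(cfg$outdir, "group_means.tsv"))
  cl_genes <- if (length(int_genes) >= cfg$k) int_genes else rownames(gm)
  cl <- kmeans_cluster(gm[cl_genes, , drop = FALSE], k = cfg$k,
                       seed = cfg$seed, standardize = cfg$standardize)
  write_tsv(data.frame(gene_id = names(cl$cluster),
                       cluster = unname(cl$cluster)),
            file.path(cfg$outdir, "clusters.tsv"))
  cs <- summarize_clusters(gm[cl_genes, , drop = FALSE], cl)
  write_tsv(cs, file.path(cfg$outdir, "cluster_summary.tsv"))
  note("cluster", cfg$k)
  stages <- list(norm = norm, log2 = lg, de_1wk = de1, de_40wk = de40,
                 overlap = ov, interaction = itab,
                 progressive = progressive, group_means = gm,
                 clusters = cl, cluster_summary = cs)

  if (!is.null(cfg$sc_counts)) {
    sc <- resolve_counts(cfg$sc_counts, format = "mtx")
    sc <- filter_sc(sc, min_genes_per_cell = 1, min_cells_per_gene = 1)
    scn <- normalize_umis(sc)
    labels <- if (is.null(cfg$sc_labels)) {
      cluster_cells(scn, seed = cfg$seed)
    } else if (is.character(cfg$sc_labels) && length(cfg$sc_labels) == 1 &&
               file.exists(cfg$sc_labels)) {
      lab <- read_tsv(cfg$sc_labels)
      stats::setNames(as.character(lab$cell_type), lab$cell_id)
    } else cfg$sc_labels
    catalog <- derive_markers(scn, labels, umi_min = cfg$umi_min,
                              min_log2fc = cfg$min_log2fc,
                              q_max = cfg$q_max, unique = cfg$unique_markers)
    write_tsv(as.data.frame(catalog), file.path(cfg$outdir, "markers.tsv"))
    note("markers", nrow(catalog))
    assign <- assign_genes(int_genes, catalog)
    write_tsv(assign, file.path(cfg$outdir, "assignments.tsv"))
    summ <- assignment_summary(assign, denominator = cfg$denominator)
    write_tsv(summ, file.path(cfg$outdir, "assignment_summary.tsv"))
    note("assignment", sum(assign$cell_type != "unassigned"))
    stages <- c(stages, list(markers = catalog, assignments = assign,
                             assignment_summary = summ))
  } else note("markers", "skipped (no single-cell input)")

  if (!is.null(cfg$gmt)) {
    sets <- if (is.character(cfg$gmt)) read_gmt(cfg$gmt) else cfg$gmt
    background <- itab$gene_id
    query <- intersect(int_genes, background)
    if (length(query)) {
      ora <- hypergeometric_ora(query, sets, background)
      write_tsv(ora, file.path(cfg$outdir, "ora.tsv"))
      note("ora", nrow(ora))
      stages$ora <- ora
    }
    ranked <- sort(stats::setNames(itab$log2fc_40wk, itab$gene_id),
                   decreasing = TRUE)
    gsea <- gsea_preranked(ranked, sets, seed = cfg$seed)
    write_tsv(gsea, file.path(cfg$outdir, "gsea.tsv"))
    note("gsea", nrow(gsea))
    stages$gsea <- gsea
  } else note("enrichment", "skipped (no gene sets)")

  man <- list(package = "wdliver",
              version = as.character(utils::packageVersion("wdliver")),
              seed = cfg$seed, preset = cfg$preset,
              thresholds = cfg[c("fc_up", "fc_down", "fdr_max",
                                 "interaction_fdr", "umi_min", "min_log2fc",
                                 "q_max", "k")],
              stages = manifest)
  yaml::write_yaml(man, file.path(cfg$outdir, "run_manifest.yaml"))
  stages$manifest <- man
  invisible(stages)
}
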