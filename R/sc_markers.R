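## Single-cell reanalysis: filtering, per-cell normalization, clustering
## (log1p -> HVG -> PCA -> kNN-graph community detection, with a k-means
## fallback), subclustering, and derivation of uniquely expressed
## cell-type marker catalogs.

#' Filter a single-cell count matrix
#'
#' Removes low-complexity cells first, then rarely detected genes, in that
#' order (so gene detection is counted over the retained cells).
#'
#' @param umis Gene x cell count matrix (dense or sparse).
#' @param min_genes_per_cell Drop cells detecting fewer genes than this.
#' @param min_cells_per_gene Drop genes detected in fewer cells than this.
#' @return The filtered gene x cell matrix.
#' @export
filter_sc <- function(umis, min_genes_per_cell = 200, min_cells_per_gene = 3) {
  detected_per_cell <- Matrix::colSums(umis > 0)
  keep_cells <- detected_per_cell >= min_genes_per_cell
  if (!any(keep_cells)) stopf("all cells removed by min_genes_per_cell = %d",
                              min_genes_per_cell)
  umis <- umis[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(umis > 0) >= min_cells_per_gene
  if (!any(keep_genes)) stopf("all genes removed by min_cells_per_gene = %d",
                              min_cells_per_gene)
  umis[keep_genes, , drop = FALSE]
}

#' Per-cell library-size normalization
#'
#' Scales each cell to a common total (counts-per-`scale`): the gene counts
#' of a cell are divided by that cell's total UMIs and multiplied by
#' `scale`. No log transform is applied; the "normalized UMI" values feed
#' the `> umi_min` marker gate directly.
#'
#' @param umis Gene x cell count matrix.
#' @param scale Target total per cell (default 10000).
#' @return Gene x cell matrix of normalized UMIs, tagged `"cp_scale"`, with
#'   the original library sizes in attribute `"lib_size"`.
#' @export
normalize_umis <- function(umis, scale = 10000) {
  if (any(umis < 0)) stopf("UMI counts must be non-negative")
  lib <- Matrix::colSums(umis)
  if (any(lib == 0)) stopf("%d cell(s) with zero total counts", sum(lib == 0))
  out <- as.matrix(umis) %*% diag(scale / lib, length(lib))
  dimnames(out) <- dimnames(umis)
  attr(out, "lib_size") <- stats::setNames(as.numeric(lib), colnames(umis))
  set_scale(out, "cp_scale")
}

# Highly variable genes by dispersion (variance/mean of normalized values).
select_hvg <- function(expr, n_hvg) {
  m <- rowMeans(expr)
  v <- row_vars(expr)
  disp <- ifelse(m > 0, v / m, 0)
  head(order(disp, decreasing = TRUE), min(n_hvg, nrow(expr)))
}

#' Cluster cells
#'
#' Standard pipeline: `log1p` of normalized values, top `n_hvg` genes by
#' dispersion, PCA to `n_pcs` components, then either Louvain community
#' detection on a shared k-nearest-neighbor graph (`method = "graph"`) or
#' k-means on the PC scores (`method = "kmeans"`). Deterministic given
#' `seed`.
#'
#' @param expr Gene x cell matrix of normalized UMIs from
#'   [normalize_umis()].
#' @param n_hvg Number of highly variable genes (default 2000, capped at
#'   the gene count).
#' @param n_pcs Number of principal components (capped at cells - 1 and the
#'   HVG count).
#' @param method `"graph"` (Louvain on a kNN graph) or `"kmeans"`.
#' @param resolution_or_k Louvain resolution (graph; default 1) or k
#'   (k-means; required).
#' @param knn Neighbors for the graph (default 15, capped at cells - 1).
#' @param seed Integer seed.
#' @return Named character vector cell -> cluster label ("1", "2", ...),
#'   with attributes `method` and `seed`.
#' @export
cluster_cells <- function(expr, n_hvg = 2000, n_pcs = 30,
                          method = c("graph", "kmeans"),
                          resolution_or_k = 1, knn = 15, seed = 1) {
  method <- match.arg(method)
  n_cells <- ncol(expr)
  if (n_cells < 2) stopf("need at least 2 cells")
  y <- log1p(as.matrix(expr))
  hvg <- select_hvg(expr, n_hvg)
  y <- y[hvg, , drop = FALSE]
  n_pcs <- min(n_pcs, n_cells - 1, nrow(y))
  if (n_pcs < 1) stopf("n_pcs must be >= 1 after capping")
  pcs <- withr::with_seed(seed,
    stats::prcomp(t(y), center = TRUE, scale. = FALSE, rank. = n_pcs)$x)
  labels <- if (method == "kmeans") {
    k <- as.integer(resolution_or_k)
    if (!is_count(k)) stopf("resolution_or_k must be a positive integer for k-means")
    if (k == 1) rep(1L, n_cells) else withr::with_seed(seed,
      stats::kmeans(pcs, centers = k, nstart = 10, iter.max = 100)$cluster)
  } else {
    k <- min(knn, n_cells - 1)
    d <- as.matrix(stats::dist(pcs))
    diag(d) <- Inf
    nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
    edges <- cbind(rep(seq_len(n_cells), each = k), as.vector(nn))
    g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
    comm <- withr::with_seed(seed,
      igraph::cluster_louvain(g, resolution = resolution_or_k))
    igraph::membership(comm)
  }
  # relabel by descending cluster size for stability
  sizes <- table(labels)
  relabel <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                             names(sizes))
  out <- stats::setNames(as.character(relabel[as.character(labels)]),
                         colnames(expr))
  attr(out, "method") <- method
  attr(out, "seed") <- seed
  out
}

#' Derive uniquely expressed cell-type markers
#'
#' For each cluster and gene, the mean normalized UMI within the cluster is
#' compared with the rest of the cells. A gene is a candidate marker for a
#' cluster when its within-cluster mean exceeds `umi_min`, the one-sided
#' Wilcoxon rank-sum test (cluster vs rest, BH-adjusted within cluster)
#' gives `q <= q_max`, and the log2 fold change versus the rest is at least
#' `min_log2fc`. With `unique = TRUE` (the default) a gene is retained only
#' if it is a candidate for exactly one cluster and its mean exceeds
#' `umi_other_max` in no other cluster, guaranteeing pairwise-disjoint
#' marker sets. The exclusion ceiling is a separate parameter (not
#' `umi_min` itself) so that tightening the own-cluster gate can only
#' shrink the catalog.
#'
#' @param expr Gene x cell matrix of normalized UMIs.
#' @param labels Named vector cell -> cluster/cell-type label covering all
#'   cells of `expr`; clusters with fewer than 2 cells are skipped with a
#'   warning.
#' @param umi_min Mean normalized UMI a marker must exceed in its own
#'   cluster (default 1.0).
#' @param min_log2fc Minimum log2 fold change vs the rest (default 1.0).
#' @param q_max BH FDR ceiling for the rank-sum test (default 0.05).
#' @param unique Enforce the uniqueness guarantee (default TRUE).
#' @param umi_other_max Mean normalized UMI above which a gene counts as
#'   expressed in a foreign cluster, disqualifying it as unique (default
#'   1.0).
#' @param eps Offset guarding the fold-change ratio (default 1e-9).
#' @return A data.frame of class `marker_catalog` with columns `cell_type`,
#'   `gene_id`, `mean_norm_umi`, `log2fc_vs_rest`, `q_value`, ordered by
#'   cell type then descending fold change; attribute `unique` records the
#'   guarantee and `gene_universe` the genes tested.
#' @export
derive_markers <- function(expr, labels, umi_min = 1, min_log2fc = 1,
                           q_max = 0.05, unique = TRUE, umi_other_max = 1,
                           eps = 1e-9) {
  expr <- as.matrix(expr)
  if (!all(colnames(expr) %in% names(labels)))
    stopf("labels must cover every cell in expr")
  labels <- labels[colnames(expr)]
  types <- sort(unique(as.character(labels)))
  if (length(types) < 2) stopf("need >= 2 clusters to derive markers")
  sizes <- table(as.character(labels))
  usable <- names(sizes)[sizes >= 2]
  if (length(usable) < length(types))
    warnf("skipping cluster(s) with < 2 cells: %s",
          paste(setdiff(types, usable), collapse = ", "))
  if (length(usable) < 2) stopf("fewer than 2 clusters with >= 2 cells")

  means <- vapply(types, function(ty)
    rowMeans(expr[, labels == ty, drop = FALSE]), numeric(nrow(expr)))
  rows <- list()
  cand_count <- stats::setNames(integer(nrow(expr)), rownames(expr))
  for (ty in usable) {
    in_ty <- labels == ty
    m_in <- means[, ty]
    m_rest <- rowMeans(expr[, !in_ty, drop = FALSE])
    lfc <- log2((m_in + eps) / (m_rest + eps))
    # p for every gene so the BH universe is fixed (keeps the catalog
    # monotone in umi_min); the expression gates are applied afterwards
    p <- vapply(seq_len(nrow(expr)), function(g)
      suppressWarnings(stats::wilcox.test(
        expr[g, in_ty], expr[g, !in_ty], alternative = "greater")$p.value),
      numeric(1))
    q <- bh_fdr(p)
    hit <- which(!is.na(q) & q <= q_max & m_in > umi_min & lfc >= min_log2fc)
    if (length(hit)) {
      cand_count[hit] <- cand_count[hit] + 1L
      rows[[ty]] <- data.frame(cell_type = ty,
                               gene_id = rownames(expr)[hit],
                               mean_norm_umi = m_in[hit],
                               log2fc_vs_rest = lfc[hit],
                               q_value = q[hit],
                               row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  cat <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_type = character(0), gene_id = character(0),
               mean_norm_umi = numeric(0), log2fc_vs_rest = numeric(0),
               q_value = numeric(0), stringsAsFactors = FALSE)
  if (unique && nrow(cat)) {
    keep <- vapply(seq_len(nrow(cat)), function(i) {
      g <- cat$gene_id[i]; ty <- cat$cell_type[i]
      cand_count[g] == 1L && all(means[g, setdiff(types, ty)] <= umi_other_max)
    }, logical(1))
    cat <- cat[keep, , drop = FALSE]
  }
  cat <- cat[order(cat$cell_type, -cat$log2fc_vs_rest, cat$gene_id), ,
             drop = FALSE]
  rownames(cat) <- NULL
  structure(cat, unique = unique, gene_universe = rownames(expr),
            class = c("marker_catalog", "data.frame"))
}

#' Subcluster the cells of one parent type
#'
#' Re-runs [cluster_cells()] on the subset of cells labeled `parent_type`;
#' the sub-labels are namespaced `parent_type/sub_i` while every other cell
#' keeps its original label.
#'
#' @param expr Gene x cell matrix of normalized UMIs (all cells).
#' @param labels Named vector cell -> label.
#' @param parent_type Label whose cells are re-clustered.
#' @param ... Passed to [cluster_cells()] (method, resolution_or_k, seed,
#'   ...).
#' @return Updated named label vector.
#' @export
subcluster <- function(expr, labels, parent_type, ...) {
  labels <- labels[colnames(expr)]
  in_parent <- labels == parent_type
  if (!any(in_parent)) stopf("no cells labeled '%s'", parent_type)
  sub <- cluster_cells(expr[, in_parent, drop = FALSE], ...)
  out <- as.character(labels)
  names(out) <- names(labels)
  out[in_parent] <- paste0(parent_type, "/sub_", sub)
  out
}
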