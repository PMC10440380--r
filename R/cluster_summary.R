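## Per-group geometric means, k-means clustering of interaction genes, and
## per-cluster single-value summaries (the heatmap/bar-plot stage).

#' Per-group geometric mean expression
#'
#' For each gene and each of the four diet x time groups, the geometric
#' mean on the normalized scale: `2^(mean of log2(v + pseudocount)) -
#' pseudocount`, floored at 0.
#'
#' @param expr Gene x sample matrix on the normalized (linear) scale.
#' @param design Design table; all four diet x time groups must be present.
#' @param pseudocount Non-negative offset guarding `log2(0)` (default 1;
#'   with 0, any zero value makes the group's geometric mean 0).
#' @return Gene x group matrix with columns `LFD-1wk`, `WD-1wk`,
#'   `LFD-40wk`, `WD-40wk`, tagged `"geomean"`.
#' @export
group_geometric_means <- function(expr, design, pseudocount = 1) {
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  grp <- design_groups(design)
  if (any(table(grp) == 0))
    stopf("missing diet x time group: need all of %s",
          paste(GROUP_LEVELS, collapse = ", "))
  lg <- log2(as.matrix(expr)[, design$sample_id, drop = FALSE] + pseudocount)
  out <- vapply(GROUP_LEVELS, function(g)
    pmax(2^rowMeans(lg[, grp == g, drop = FALSE]) - pseudocount, 0),
    numeric(nrow(expr)))
  rownames(out) <- rownames(expr)
  set_scale(out, "geomean")
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[i + 1] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[i + 1], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[idx, , drop = FALSE]
}

#' Cluster genes by their group-mean expression profiles
#'
#' Lloyd's k-means with k-means++ seeding on (optionally) per-gene
#' row-standardized group means; the best of `n_init` restarts by total
#' within-cluster sum of squares is kept. Clusters are relabeled 1..k by
#' descending gene count, ties broken by the smallest member gene ID, so
#' labels are deterministic given the seed.
#'
#' @param means Gene x group matrix from [group_geometric_means()].
#' @param k Number of clusters (default 8).
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 10).
#' @param standardize Row-standardize each gene to mean 0, sd 1 before
#'   clustering (default TRUE; constant genes become all-zero rows).
#' @return A list of class `gene_cluster_map`: `cluster` (named integer
#'   vector gene -> 1..k), `k`, `seed`, `inertia` (best total within-cluster
#'   SS), `sizes`.
#' @export
kmeans_cluster <- function(means, k = 8, seed = 1, n_init = 10,
                           standardize = TRUE) {
  x <- as.matrix(means)
  if (!is_count(k)) stopf("k must be a positive integer")
  if (nrow(x) < k) stopf("need at least k = %d genes, got %d", k, nrow(x))
  if (standardize) {
    mu <- rowMeans(x)
    sdv <- apply(x, 1, stats::sd)
    sdv[sdv == 0] <- 1
    x <- (x - mu) / sdv
  }
  best <- NULL
  withr::with_seed(seed, {
    for (i in seq_len(n_init)) {
      fit <- tryCatch(
        stats::kmeans(x, centers = kmeanspp_centers(x, k),
                      algorithm = "Lloyd", iter.max = 100),
        error = function(e) NULL, warning = function(w) NULL)
      if (!is.null(fit) && (is.null(best) || fit$tot.withinss < best$tot.withinss))
        best <- fit
    }
  })
  if (is.null(best)) stopf("k-means failed to converge in all %d restarts", n_init)
  cl <- stats::setNames(best$cluster, rownames(x))
  # deterministic relabeling: by descending size, then smallest member ID
  first_member <- vapply(seq_len(k), function(c) {
    m <- names(cl)[cl == c]
    if (length(m)) min(m) else "~~empty~~"
  }, character(1))
  ord <- order(-tabulate(cl, k), first_member)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  structure(list(cluster = stats::setNames(relabel[cl], names(cl)),
                 k = k, seed = seed, inertia = best$tot.withinss,
                 sizes = tabulate(relabel[cl], k)),
            class = "gene_cluster_map")
}

#' Summarize clusters to a single value per group
#'
#' Entry (c, g) is the median over genes in cluster c of the group-g
#' geometric mean (even-sized clusters take the midpoint). Alternative
#' statistics `sum` and `mean` are available.
#'
#' @param means Gene x group matrix from [group_geometric_means()].
#' @param clusters A `gene_cluster_map` from [kmeans_cluster()] covering
#'   the matrix's genes.
#' @param stat Summary statistic: `"median"` (default), `"sum"` or
#'   `"mean"`.
#' @return A data.frame with one row per cluster: `cluster`, `n_genes`,
#'   then one column per group. Empty clusters yield NaN rows with a
#'   warning.
#' @export
summarize_clusters <- function(means, clusters, stat = c("median", "sum", "mean")) {
  stat <- match.arg(stat)
  fn <- switch(stat, median = stats::median, sum = sum, mean = mean)
  x <- as.matrix(means)
  cl <- clusters$cluster
  if (!all(rownames(x) %in% names(cl)))
    stopf("cluster map does not cover all genes in the matrix")
  cl <- cl[rownames(x)]
  out <- matrix(NaN, clusters$k, ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (c_i in seq_len(clusters$k)) {
    members <- which(cl == c_i)
    if (length(members) == 0) {
      warnf("cluster %d is empty: summary row set to NaN", c_i)
      next
    }
    out[c_i, ] <- apply(x[members, , drop = FALSE], 2, fn)
  }
  data.frame(cluster = seq_len(clusters$k),
             n_genes = as.integer(tabulate(cl, clusters$k)),
             out, check.names = FALSE, stringsAsFactors = FALSE)
}
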