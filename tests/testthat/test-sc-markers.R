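# Single-cell filtering, normalization, clustering, marker derivation
# (the normalized-UMI > 1 / fold-change / uniqueness rule) and
# subclustering.

test_that("cell and gene filters apply in order with sensible errors", {
  m <- matrix(0L, 5, 4, dimnames = list(paste0("g", 1:5), paste0("c", 1:4)))
  m[1:4, 1] <- 5L   # cell 1 detects 4 genes
  m[1:2, 2] <- 3L   # cell 2 detects 2
  m[1, 3] <- 1L     # cell 3 detects 1
  m[5, 4] <- 2L     # gene 5 only in cell 4

  out <- filter_sc(m, min_genes_per_cell = 2, min_cells_per_gene = 1)
  expect_setequal(colnames(out), c("c1", "c2"))
  expect_false("g5" %in% rownames(out))  # cell 4 removed first, then g5

  expect_identical(filter_sc(m, 0, 0), m)
  # genes detected in fewer than 2 of the remaining cells are removed
  out2 <- filter_sc(m, min_genes_per_cell = 2, min_cells_per_gene = 2)
  expect_setequal(rownames(out2), c("g1", "g2"))
  expect_error(filter_sc(m, min_genes_per_cell = 100), "all cells")
  expect_error(filter_sc(m, 0, 100), "all genes")
})

test_that("per-cell normalization scales every cell to the target total", {
  m <- matrix(c(1L, 999L, 0L, 50L, 25L, 25L), 3, 2,
              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
  norm <- normalize_umis(m, scale = 10000)
  expect_equal(norm["g1", "c1"], 10)            # 1/1000 x 10^4
  expect_equal(unname(colSums(norm)), c(10000, 10000))
  expect_equal(attr(norm, "lib_size"), c(c1 = 1000, c2 = 100))
  # cells already summing to scale are unchanged
  m2 <- matrix(c(4000L, 6000L), 2, 1, dimnames = list(c("a", "b"), "c1"))
  expect_equal(unname(normalize_umis(m2, scale = 10000)[, 1]), c(4000, 6000))
  m3 <- cbind(m, c3 = c(0L, 0L, 0L))
  expect_error(normalize_umis(m3), "zero total")
})

test_that("clustering recovers strongly separated simulated cell types", {
  sc <- simulate_sc_umis(sc_sim_config(n_cell_types = 2, cells_per_type = 60,
                                       n_genes = 300, markers_per_type = 30,
                                       marker_fold = 8,
                                       marker_baseline_norm = 1, seed = 21))
  norm <- normalize_umis(filter_sc(sc$counts, 1, 1))
  lab_graph <- cluster_cells(norm, n_pcs = 10, method = "graph", seed = 3)
  expect_equal(ari(lab_graph, sc$labels[names(lab_graph)]), 1.0)
  lab_km <- cluster_cells(norm, n_pcs = 10, method = "kmeans",
                          resolution_or_k = 2, seed = 3)
  expect_equal(ari(lab_km, sc$labels[names(lab_km)]), 1.0)
  # seeded determinism
  expect_identical(lab_graph,
                   cluster_cells(norm, n_pcs = 10, method = "graph", seed = 3))
  # single homogeneous population, k = 1
  one <- cluster_cells(norm, n_pcs = 5, method = "kmeans",
                       resolution_or_k = 1, seed = 1)
  expect_equal(length(unique(one)), 1L)
})

test_that("marker derivation enforces the UMI, fold-change and uniqueness gates", {
  set.seed(22)
  n_per <- 25
  labels <- setNames(rep(c("A", "B", "C"), each = n_per),
                     sprintf("c%02d", 1:(3 * n_per)))
  mk_gene <- function(mean_by_type) unlist(lapply(mean_by_type, function(m)
    rpois(n_per, m)))
  expr <- rbind(
    marker_a = mk_gene(c(20, 0.2, 0.2)),  # high in A only
    shared_ab = mk_gene(c(30, 25, 1)),  # high in A and B: not unique
    low_best = mk_gene(c(0.5, 0.05, 0.05)),  # best mean below umi_min
    flat = mk_gene(c(5, 5, 5)))
  colnames(expr) <- names(labels)
  expr <- wdliver:::set_scale(expr, "cp_scale")

  cat_u <- derive_markers(expr, labels, umi_min = 1, min_log2fc = 1,
                          q_max = 0.05, unique = TRUE)
  expect_identical(cat_u$gene_id, "marker_a")
  expect_identical(cat_u$cell_type, "A")
  expect_gt(cat_u$mean_norm_umi, 1)

  cat_nu <- derive_markers(expr, labels, unique = FALSE)
  expect_true("shared_ab" %in% cat_nu$gene_id)   # candidate without uniqueness
  expect_false("low_best" %in% cat_nu$gene_id)   # fails UMI > 1 gate
  expect_false("flat" %in% cat_nu$gene_id)
})

test_that("unique catalogs are pairwise disjoint and monotone in umi_min", {
  sc <- simulate_sc_umis(sc_sim_config(n_cell_types = 3, cells_per_type = 40,
                                       n_genes = 250, markers_per_type = 15,
                                       marker_fold = 8, seed = 23))
  norm <- normalize_umis(sc$counts)
  prev <- NULL
  for (gate in c(0.5, 1, 2, 4)) {
    cat <- derive_markers(norm, sc$labels, umi_min = gate)
    expect_false(anyDuplicated(cat$gene_id) > 0)
    if (!is.null(prev))
      expect_true(all(paste(cat$cell_type, cat$gene_id) %in% prev))
    prev <- paste(cat$cell_type, cat$gene_id)
  }
})

test_that("rank-sum p-values agree with exact permutation enumeration", {
  # the marker test uses the one-sided Wilcoxon rank-sum; for groups <= 6
  # without ties it must match brute-force enumeration of group splits
  enum_p <- function(x, y) {
    pooled <- c(x, y); n <- length(x)
    w_obs <- sum(rank(pooled)[seq_len(n)])
    splits <- utils::combn(length(pooled), n)
    w_all <- apply(splits, 2, function(idx) sum(rank(pooled)[idx]))
    mean(w_all >= w_obs)
  }
  set.seed(24)
  for (i in 1:5) {
    x <- sample(100, sample(3:6, 1))
    y <- sample(200, sample(3:6, 1))
    got <- stats::wilcox.test(x, y, alternative = "greater")$p.value
    expect_equal(got, enum_p(x, y), tolerance = 1e-12)
  }
})

test_that("derived markers vanish when no signal is planted", {
  empties <- vapply(1:20, function(s) {
    sc <- simulate_sc_umis(sc_sim_config(n_cell_types = 3, cells_per_type = 30,
                                         n_genes = 200, markers_per_type = 10,
                                         marker_fold = 1, seed = s))
    nrow(derive_markers(normalize_umis(sc$counts), sc$labels)) == 0
  }, logical(1))
  expect_gte(mean(empties), 0.9)
})

test_that("subclustering namespaces the parent and leaves other cells alone", {
  # two parent types; type01 secretly contains two subtypes, built by
  # stacking two separately simulated populations over the same genes
  sub <- simulate_sc_umis(sc_sim_config(n_cell_types = 2, cells_per_type = 40,
                                        n_genes = 300, markers_per_type = 25,
                                        marker_fold = 8,
                                        marker_baseline_norm = 1, seed = 31))
  other <- simulate_sc_umis(sc_sim_config(n_cell_types = 1, cells_per_type = 40,
                                          n_genes = 300, markers_per_type = 10,
                                          marker_fold = 8, seed = 32))
  colnames(other$counts) <- paste0("o_", colnames(other$counts))
  counts <- cbind(sub$counts, other$counts)
  labels <- setNames(c(rep("parent", ncol(sub$counts)),
                       rep("other", ncol(other$counts))), colnames(counts))
  norm <- normalize_umis(counts)
  out <- subcluster(norm, labels, "parent", method = "kmeans",
                    resolution_or_k = 2, n_pcs = 10, seed = 7)
  expect_true(all(out[colnames(other$counts)] == "other"))
  sub_labels <- out[colnames(sub$counts)]
  expect_true(all(startsWith(sub_labels, "parent/sub_")))
  expect_equal(ari(sub_labels, sub$labels), 1.0)
  # homogeneous parent with k = 1 stays a single subcluster
  one <- subcluster(norm, labels, "other", method = "kmeans",
                    resolution_or_k = 1, n_pcs = 5, seed = 7)
  expect_equal(length(unique(one[colnames(other$counts)])), 1L)
  expect_error(subcluster(norm, labels, "missing_type"), "no cells")
})
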