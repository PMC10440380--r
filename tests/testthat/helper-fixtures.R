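# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

# Minimal 2x2 design with n samples per diet x time cell (sexes alternate).
make_design <- function(n_per_cell = 3) {
  cells <- expand.grid(rep_i = seq_len(n_per_cell),
                       diet = c("LFD", "WD"), time = c(1L, 40L),
                       stringsAsFactors = FALSE)
  data.frame(sample_id = sprintf("%s_%d_%d", cells$diet, cells$time, cells$rep_i),
             diet = cells$diet, time = cells$time,
             sex = rep(c("F", "M"), length.out = nrow(cells)),
             stringsAsFactors = FALSE)
}

# Gaussian log2 expression with optional per-gene interaction shift in the
# WD-40wk cell only (the study-condition null/alternative generator used
# for FDR calibration checks).
make_gaussian_expr <- function(design, n_genes, sd = 0.5, n_interaction = 0,
                               effect = 1, baseline = 5) {
  ids <- sprintf("g%04d", seq_len(n_genes))
  m <- matrix(stats::rnorm(n_genes * nrow(design), baseline, sd),
              n_genes, nrow(design), dimnames = list(ids, design$sample_id))
  if (n_interaction > 0) {
    wd40 <- design$diet == "WD" & design$time == 40
    m[seq_len(n_interaction), wd40] <- m[seq_len(n_interaction), wd40] + effect
  }
  attr(m, "true_interaction") <- ids[seq_len(n_interaction)]
  wdliver:::set_scale(m, "log2")
}

# Linked bulk + single-cell fixture: the single-cell marker genes are
# planted as bulk interaction genes, so end-to-end cell-type recovery has
# a known answer.
make_linked_fixture <- function(seed = 1, n_genes = 600, n_types = 4,
                                cells_per_type = 60, markers_per_type = 20,
                                marker_fold = 8) {
  sc <- simulate_sc_umis(sc_sim_config(
    n_cell_types = n_types, cells_per_type = cells_per_type,
    n_genes = n_genes, markers_per_type = markers_per_type,
    marker_fold = marker_fold, library_size_mean = 4000, seed = seed))
  marker_genes <- sc$truth$gene_id[sc$truth$origin_cell_type != "none"]
  origin <- stats::setNames(
    sc$truth$origin_cell_type[sc$truth$origin_cell_type != "none"],
    marker_genes)
  bulk <- simulate_bulk_counts(
    bulk_sim_config(n_genes = n_genes,
                    frac_interaction = length(marker_genes) / n_genes,
                    frac_de_main = 0.05, effect_log2_interaction = 2,
                    nb_dispersion = 0.1, seed = seed + 1000),
    gene_ids = sc$truth$gene_id, interaction_genes = marker_genes,
    origin_map = origin)
  list(bulk = bulk, sc = sc, marker_genes = marker_genes, origin = origin)
}

# Adjusted Rand index between two labelings (permutation-invariant).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

expect_file_md5_equal <- function(f1, f2) {
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
}
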