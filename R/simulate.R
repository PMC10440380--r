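## Synthetic-data generators: negative-binomial bulk counts in the 2x2x2
## diet x time x sex design, and a clustered single-cell UMI matrix with
## planted cell-type-unique markers. Every generator is a pure function of
## its config (including the seed) and returns a ground-truth ledger.

#' Bulk simulation configuration
#'
#' Emulates the study design: two sexes, two diets (LFD/WD), two timepoints
#' (1 and 40 weeks), with 4 LFD and 8 WD mice per sex per timepoint.
#' Counts are negative binomial around group means shifted on the log2
#' scale by planted effects; per-sample library sizes vary log-normally
#' (sd 0.2) to exercise quantile normalization.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_per_group_lfd,n_per_group_wd Mice per sex per timepoint on each
#'   diet (defaults 4 and 8, the study's group sizes).
#' @param frac_de_main Fraction of genes given a diet main effect (present
#'   at both timepoints), sign random.
#' @param frac_interaction Fraction of genes given a diet x time interaction
#'   effect: the shift applies only in the WD 40-week cell, mimicking genes
#'   progressively induced by the diet.
#' @param effect_log2_main,effect_log2_interaction Planted effect sizes in
#'   log2 units.
#' @param baseline_log2_mean_range Interval the per-gene baseline log2 mean
#'   is drawn from (uniform).
#' @param nb_dispersion Negative-binomial dispersion shared across genes
#'   (`size = 1/dispersion`).
#' @param libsize_log_sd Log-normal sd of the per-sample scaling factor.
#' @param seed Integer seed; identical configs give bit-identical output.
#' @return A `bulk_sim_config` list, validated.
#' @export
bulk_sim_config <- function(n_genes = 2000, n_per_group_lfd = 4,
                            n_per_group_wd = 8, frac_de_main = 0.1,
                            frac_interaction = 0.1, effect_log2_main = 1,
                            effect_log2_interaction = 2,
                            baseline_log2_mean_range = c(3, 10),
                            nb_dispersion = 0.1, libsize_log_sd = 0.2,
                            seed = 1) {
  if (!is_count(n_genes) || !is_count(n_per_group_lfd) || !is_count(n_per_group_wd))
    stopf("n_genes and group sizes must be positive integers")
  fr <- c(frac_de_main, frac_interaction)
  if (any(fr < 0 | fr > 1) || sum(fr) > 1)
    stopf("fractions must lie in [0,1] and sum to at most 1")
  if (nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  if (length(baseline_log2_mean_range) != 2 ||
      diff(baseline_log2_mean_range) < 0)
    stopf("baseline_log2_mean_range must be an increasing interval")
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group_lfd = as.integer(n_per_group_lfd),
                 n_per_group_wd = as.integer(n_per_group_wd),
                 frac_de_main = frac_de_main,
                 frac_interaction = frac_interaction,
                 effect_log2_main = effect_log2_main,
                 effect_log2_interaction = effect_log2_interaction,
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 nb_dispersion = nb_dispersion,
                 libsize_log_sd = libsize_log_sd,
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Simulate bulk RNA-seq counts with known ground truth
#'
#' @param config A [bulk_sim_config()].
#' @param gene_ids Optional character vector of gene IDs (length `n_genes`);
#'   defaults to `gene0001`, ... Used to share a gene universe with a
#'   single-cell simulation.
#' @param interaction_genes Optional gene IDs to receive the interaction
#'   effect instead of a random draw; its length then overrides
#'   `round(frac_interaction * n_genes)`.
#' @param origin_map Optional named character vector `gene_id -> cell type`
#'   recorded in the truth ledger's `origin_cell_type` column (default
#'   `"none"` everywhere); purely bookkeeping for linked bulk/single-cell
#'   fixtures.
#' @return A list with `counts` (integer gene x sample matrix), `design`
#'   (data.frame: sample_id, diet, time, sex) and `truth` (per-gene ledger:
#'   flags `is_de_1wk`, `is_de_40wk`, `is_interaction`, true log2 fold
#'   changes per timepoint, `origin_cell_type`).
#' @export
simulate_bulk_counts <- function(config, gene_ids = NULL,
                                 interaction_genes = NULL, origin_map = NULL) {
  stopifnot(inherits(config, "bulk_sim_config"))
  cfg <- config
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  if (length(gene_ids) != cfg$n_genes || anyDuplicated(gene_ids))
    stopf("gene_ids must be %d unique IDs", cfg$n_genes)

  design <- expand.grid(rep_i = seq_len(max(cfg$n_per_group_lfd, cfg$n_per_group_wd)),
                        sex = c("F", "M"), diet = c("LFD", "WD"),
                        time = c(1L, 40L), stringsAsFactors = FALSE)
  n_per <- ifelse(design$diet == "LFD", cfg$n_per_group_lfd, cfg$n_per_group_wd)
  design <- design[design$rep_i <= n_per, , drop = FALSE]
  design <- data.frame(
    sample_id = sprintf("%s_%dwk_%s_%02d", design$diet, design$time,
                        design$sex, design$rep_i),
    diet = design$diet, time = design$time, sex = design$sex,
    stringsAsFactors = FALSE)

  n_main <- round(cfg$frac_de_main * cfg$n_genes)
  n_int  <- round(cfg$frac_interaction * cfg$n_genes)

  withr::with_seed(cfg$seed, {
    if (is.null(interaction_genes)) {
      picks <- sample(gene_ids, n_main + n_int)
      main_genes <- picks[seq_len(n_main)]
      interaction_genes <- picks[n_main + seq_len(n_int)]
    } else {
      if (!all(interaction_genes %in% gene_ids))
        stopf("interaction_genes must be a subset of gene_ids")
      main_genes <- sample(setdiff(gene_ids, interaction_genes), n_main)
    }
    baseline <- stats::runif(cfg$n_genes, cfg$baseline_log2_mean_range[1],
                             cfg$baseline_log2_mean_range[2])
    names(baseline) <- gene_ids
    main_sign <- sample(c(-1, 1), length(main_genes), replace = TRUE)

    fc1 <- fc40 <- stats::setNames(numeric(cfg$n_genes), gene_ids)
    fc1[main_genes] <- fc40[main_genes] <- main_sign * cfg$effect_log2_main
    fc40[interaction_genes] <- cfg$effect_log2_interaction

    # log2 group mean per gene/sample; interaction shift only in WD-40wk.
    is_wd <- design$diet == "WD"
    shift <- outer(fc1, as.numeric(is_wd & design$time == 1L)) +
      outer(fc40, as.numeric(is_wd & design$time == 40L))
    log2_mu <- baseline + shift
    sf <- stats::rlnorm(nrow(design), 0, cfg$libsize_log_sd)
    mu <- 2^log2_mu * rep(sf, each = cfg$n_genes)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = cfg$n_genes,
      dimnames = list(gene_ids, design$sample_id))
    storage.mode(counts) <- "integer"
  })

  origin <- rep("none", cfg$n_genes)
  names(origin) <- gene_ids
  if (!is.null(origin_map)) origin[names(origin_map)] <- origin_map

  truth <- data.frame(
    gene_id = gene_ids,
    is_de_1wk = gene_ids %in% main_genes,
    is_de_40wk = gene_ids %in% c(main_genes, interaction_genes),
    is_interaction = gene_ids %in% interaction_genes,
    true_log2fc_1wk = unname(fc1), true_log2fc_40wk = unname(fc40),
    origin_cell_type = unname(origin),
    row.names = NULL, stringsAsFactors = FALSE)

  list(counts = counts, design = design, truth = truth)
}

#' Single-cell simulation configuration
#'
#' Emulates a clustered liver single-cell UMI matrix: each cell type has a
#' disjoint block of marker genes whose expected expression is
#' `marker_fold` times baseline in its own type only.
#'
#' @param n_cell_types Number of cell types.
#' @param cells_per_type Cells simulated per type.
#' @param n_genes Total genes.
#' @param markers_per_type Planted unique markers per type
#'   (`markers_per_type * n_cell_types <= n_genes`).
#' @param marker_fold Expected fold elevation of a marker in its own type
#'   (> 1 plants signal; 1 is the null).
#' @param marker_baseline_norm Baseline expression of marker genes outside
#'   their own type, in normalized units at the counts-per-10000 scale
#'   (default 0.25). Markers are near-silent elsewhere, as cell-type-unique
#'   genes are in real tissue; their own-type level is
#'   `marker_fold * marker_baseline_norm`.
#' @param library_size_mean Mean UMIs per cell (Poisson-distributed totals).
#' @param nb_dispersion Gene-level negative-binomial dispersion.
#' @param seed Integer seed.
#' @return An `sc_sim_config` list, validated.
#' @export
sc_sim_config <- function(n_cell_types = 12, cells_per_type = 150,
                          n_genes = 2000, markers_per_type = 40,
                          marker_fold = 8, marker_baseline_norm = 0.25,
                          library_size_mean = 5000,
                          nb_dispersion = 0.5, seed = 1) {
  if (!is_count(n_cell_types) || !is_count(cells_per_type) ||
      !is_count(n_genes) || !is_count(markers_per_type))
    stopf("counts in sc_sim_config must be positive integers")
  if (markers_per_type * n_cell_types > n_genes)
    stopf("markers_per_type * n_cell_types must not exceed n_genes")
  if (marker_fold < 1) stopf("marker_fold must be >= 1")
  if (marker_baseline_norm <= 0)
    stopf("marker_baseline_norm must be positive")
  if (nb_dispersion <= 0 || library_size_mean <= 0)
    stopf("dispersion and library size must be positive")
  structure(list(n_cell_types = as.integer(n_cell_types),
                 cells_per_type = as.integer(cells_per_type),
                 n_genes = as.integer(n_genes),
                 markers_per_type = as.integer(markers_per_type),
                 marker_fold = marker_fold,
                 marker_baseline_norm = marker_baseline_norm,
                 library_size_mean = library_size_mean,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "sc_sim_config")
}

#' Simulate a single-cell UMI matrix with planted markers
#'
#' Cell totals are Poisson around `library_size_mean`; within a cell, gene
#' means follow per-gene baseline weights (log-normal) with each marker
#' block multiplied by `marker_fold` in its own type, renormalized to the
#' cell total, and counts drawn negative-binomially.
#'
#' @param config An [sc_sim_config()].
#' @param gene_ids Optional gene IDs (length `n_genes`).
#' @return A list with `counts` (integer gene x cell matrix), `labels`
#'   (named character vector cell -> true type `type01`, ...) and `truth`
#'   (per-gene `origin_cell_type`, `"none"` for non-markers).
#' @export
simulate_sc_umis <- function(config, gene_ids = NULL) {
  stopifnot(inherits(config, "sc_sim_config"))
  cfg <- config
  if (is.null(gene_ids))
    gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  if (length(gene_ids) != cfg$n_genes || anyDuplicated(gene_ids))
    stopf("gene_ids must be %d unique IDs", cfg$n_genes)
  types <- sprintf("type%02d", seq_len(cfg$n_cell_types))
  n_cells <- cfg$n_cell_types * cfg$cells_per_type
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  labels <- stats::setNames(rep(types, each = cfg$cells_per_type), cell_ids)

  withr::with_seed(cfg$seed, {
    marker_pick <- sample(gene_ids, cfg$markers_per_type * cfg$n_cell_types)
    marker_of <- stats::setNames(rep("none", cfg$n_genes), gene_ids)
    marker_of[marker_pick] <- rep(types, each = cfg$markers_per_type)
    base_w <- stats::rlnorm(cfg$n_genes, 0, 1)
    # Marker genes sit on a low common baseline calibrated so that their
    # foreign-type expression lands near marker_baseline_norm normalized
    # units (at the counts-per-10000 scale) after library scaling.
    is_marker <- marker_of != "none"
    base_w[is_marker] <- cfg$marker_baseline_norm *
      sum(base_w[!is_marker]) / 1e4
    # Expected fraction per gene within each type: marker block scaled up.
    w <- matrix(base_w, cfg$n_genes, cfg$n_cell_types,
                dimnames = list(gene_ids, types))
    for (ty in types)
      w[marker_of == ty, ty] <- w[marker_of == ty, ty] * cfg$marker_fold
    w <- sweep(w, 2, colSums(w), "/")
    lib <- stats::rpois(n_cells, cfg$library_size_mean)
    mu <- w[, labels, drop = FALSE] * rep(lib, each = cfg$n_genes)
    counts <- matrix(
      stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
      nrow = cfg$n_genes, dimnames = list(gene_ids, cell_ids))
    storage.mode(counts) <- "integer"
  })

  truth <- data.frame(gene_id = gene_ids,
                      origin_cell_type = unname(marker_of[gene_ids]),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(counts = counts, labels = labels, truth = truth)
}

#' Write a fixture bundle to disk
#'
#' Writes the bulk counts/design/truth as TSV and the single-cell matrix as
#' a MatrixMarket triplet with gene/barcode sidecars plus labels and truth
#' TSVs. Everything round-trips losslessly through [read_counts()],
#' [read_design()] and [read_tsv] semantics.
#'
#' @param dir Output directory (created if missing).
#' @param bulk List from [simulate_bulk_counts()] (or NULL to skip).
#' @param sc List from [simulate_sc_umis()] (or NULL to skip).
#' @return Invisibly, the named character vector of files written.
#' @export
write_fixture_bundle <- function(dir, bulk = NULL, sc = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create directory '%s'", dir)
  files <- character(0)
  if (!is.null(bulk)) {
    files["counts"] <- write_counts_tsv(bulk$counts, file.path(dir, "bulk_counts.tsv"))
    files["design"] <- write_tsv(bulk$design, file.path(dir, "bulk_design.tsv"))
    files["truth"] <- write_tsv(bulk$truth, file.path(dir, "bulk_truth.tsv"))
  }
  if (!is.null(sc)) {
    m <- file.path(dir, "sc_matrix.mtx")
    Matrix::writeMM(methods::as(Matrix::Matrix(sc$counts, sparse = TRUE), "generalMatrix"), m)
    writeLines(rownames(sc$counts), file.path(dir, "sc_genes.tsv"))
    writeLines(colnames(sc$counts), file.path(dir, "sc_barcodes.tsv"))
    files["sc_matrix"] <- m
    files["sc_genes"] <- file.path(dir, "sc_genes.tsv")
    files["sc_barcodes"] <- file.path(dir, "sc_barcodes.tsv")
    files["sc_labels"] <- write_tsv(
      data.frame(cell_id = names(sc$labels), cell_type = unname(sc$labels),
                 stringsAsFactors = FALSE),
      file.path(dir, "sc_labels.tsv"))
    files["sc_truth"] <- write_tsv(sc$truth, file.path(dir, "sc_truth.tsv"))
  }
  invisible(files)
}
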