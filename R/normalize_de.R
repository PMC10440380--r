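## Bulk normalization and the two differential-expression screens:
## per-timepoint WD/LFD comparison and the diet x time interaction test.

#' Quantile normalize a count matrix
#'
#' Forces every sample (column) onto the identical distribution: each
#' column's sorted values are replaced by the row-wise mean of all columns'
#' sorted values; ties within a column receive the mean of the reference
#' values at their rank positions.
#'
#' @param counts Numeric gene x sample matrix, non-negative, with at least
#'   two columns. Row names are gene IDs, column names sample IDs.
#' @return A matrix of the same dimension tagged `"normalized"`; after
#'   normalization the sorted value vectors of all columns are identical.
#' @export
quantile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2)
    stopf("quantile normalization needs >= 2 samples, got %d", ncol(counts))
  if (any(counts < 0, na.rm = TRUE))
    stopf("counts must be non-negative")
  out <- limma::normalizeQuantiles(counts, ties = TRUE)
  dimnames(out) <- dimnames(counts)
  set_scale(out, "normalized")
}

#' Log2-transform an expression matrix
#'
#' @param expr Non-negative numeric matrix.
#' @param pseudocount Positive offset added before taking log2 so zeros map
#'   to a finite value (default 1, so a zero maps to 0).
#' @return `log2(expr + pseudocount)`, tagged `"log2"`, with the pseudocount
#'   recorded in attribute `"pseudocount"`.
#' @export
log2_transform <- function(expr, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0)
    stopf("pseudocount must be a positive scalar")
  if (any(expr < 0, na.rm = TRUE)) stopf("expression values must be >= 0")
  out <- log2(as.matrix(expr) + pseudocount)
  attr(out, "pseudocount") <- pseudocount
  set_scale(out, "log2")
}

#' Benjamini-Hochberg q-values
#'
#' Step-up adjustment `q_(i) = min_{j>=i}(p_(j) * m / j)` capped at 1 and
#' mapped back to input order. `NA`/`NaN` entries are passed through
#' unchanged and excluded from the ranking (`m` counts only finite values).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (!is.numeric(p_values)) stopf("p_values must be numeric")
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stopf("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p_values))
  q[ok] <- stats::p.adjust(p_values[ok], method = "BH")
  q
}

# Vectorized Welch two-sample t-test by rows of a log2 matrix.
welch_rows <- function(x_a, x_b) {
  na <- ncol(x_a); nb <- ncol(x_b)
  ma <- rowMeans(x_a); mb <- rowMeans(x_b)
  va <- row_vars(x_a); vb <- row_vars(x_b)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  zero <- se2 == 0
  tstat[zero] <- NA_real_; p[zero] <- NA_real_; df[zero] <- NA_real_
  list(t = tstat, df = df, p = p, mean_a = ma, mean_b = mb, n_zero_var = sum(zero))
}

#' Per-timepoint WD vs LFD differential expression
#'
#' Welch's unpaired t-test per gene on log2 expression, WD versus LFD at one
#' timepoint with sexes pooled as replicates (or stratified with `by_sex`).
#' A gene is called `up` when `fold_change >= fc_up` and `q <= fdr_max`,
#' `down` when `fold_change <= fc_down` and `q <= fdr_max` (thresholds
#' inclusive), otherwise `ns`.
#'
#' @param expr Gene x sample matrix on the log2 scale (see
#'   [log2_transform()]).
#' @param design Design table with columns `sample_id`, `diet` (LFD/WD),
#'   `time` (1/40), `sex` (F/M); see [read_design()].
#' @param time Timepoint to test, 1 or 40 (weeks).
#' @param fc_up,fc_down Fold-change gates for up/down calls (defaults 2 and
#'   0.5, i.e. a two-fold change in either direction).
#' @param fdr_max FDR ceiling for a call (default 0.1).
#' @param by_sex If `TRUE`, analyze each sex separately and return a list of
#'   two tables; default pools sexes.
#' @return A data.frame with one row per gene: `gene_id`, `mean_expr_lfd`
#'   and `mean_expr_wd` (geometric means on the normalized scale),
#'   `fold_change` (WD/LFD), `log2fc`, `t_stat`, `p_value`, `q_value`,
#'   `call`. Genes with zero variance in both groups get `p = NA`,
#'   `call = "ns"` and a warning.
#' @export
de_per_timepoint <- function(expr, design, time, fc_up = 2, fc_down = 0.5,
                             fdr_max = 0.1, by_sex = FALSE) {
  time <- as.integer(time)
  if (!time %in% c(1L, 40L)) stopf("time must be 1 or 40")
  if (isTRUE(by_sex)) {
    out <- lapply(split(design, design$sex), function(d)
      de_per_timepoint(expr[, d$sample_id, drop = FALSE], d, time,
                       fc_up, fc_down, fdr_max))
    return(out)
  }
  sel <- design[design$time == time, , drop = FALSE]
  lfd <- sel$sample_id[sel$diet == "LFD"]
  wd  <- sel$sample_id[sel$diet == "WD"]
  if (length(lfd) < 2 || length(wd) < 2)
    stopf("need >= 2 samples per diet at %d weeks (LFD: %d, WD: %d)",
          time, length(lfd), length(wd))
  w <- welch_rows(expr[, wd, drop = FALSE], expr[, lfd, drop = FALSE])
  if (w$n_zero_var > 0)
    warnf("%d gene(s) with zero within-group variance at %d weeks: p set to NA, call ns",
          w$n_zero_var, time)
  log2fc <- w$mean_a - w$mean_b
  q <- bh_fdr(w$p)
  fc <- 2^log2fc
  call <- rep("ns", nrow(expr))
  call[!is.na(q) & fc >= fc_up & q <= fdr_max] <- "up"
  call[!is.na(q) & fc <= fc_down & q <= fdr_max] <- "down"
  data.frame(gene_id = rownames(expr),
             mean_expr_lfd = 2^w$mean_b, mean_expr_wd = 2^w$mean_a,
             fold_change = fc, log2fc = log2fc,
             t_stat = w$t, p_value = w$p, q_value = q, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Per-timepoint WD - LFD difference of log2 group means, sexes pooled.
timepoint_log2fc <- function(expr, design, time) {
  sel <- design[design$time == time, , drop = FALSE]
  rowMeans(expr[, sel$sample_id[sel$diet == "WD"], drop = FALSE]) -
    rowMeans(expr[, sel$sample_id[sel$diet == "LFD"], drop = FALSE])
}

#' Diet x time interaction screen (two-way ANOVA)
#'
#' Fixed-effects 2x2 ANOVA per gene on log2 expression. The interaction F
#' compares the full cell-means model against the additive diet + time
#' model: `F = (SSE_additive - SSE_full) / (SSE_full / (N - 4))` on
#' df (1, N - 4), which reduces to `MS_interaction / MS_within` in the
#' balanced case and remains the correct interaction-last test when the
#' cells are unbalanced (e.g. 4 LFD vs 8 WD mice per sex). Sexes are pooled
#' as replicates within the four diet x time cells.
#'
#' @inheritParams de_per_timepoint
#' @return A data.frame per gene: `gene_id`, `F_stat`, `p_value`, `q_value`
#'   (BH across genes), `log2fc_1wk`, `log2fc_40wk` (WD - LFD log2 group
#'   mean difference per timepoint). Genes with zero residual variance get
#'   `p = NA`.
#' @export
interaction_test <- function(expr, design) {
  grp <- design_groups(design)
  tab <- table(grp)
  if (any(tab < 2))
    stopf("every diet x time cell needs >= 2 samples; got [%s]",
          paste(tab, collapse = ", "))
  expr <- expr[, design$sample_id, drop = FALSE]
  n <- ncol(expr)
  diet <- factor(design$diet, levels = c("LFD", "WD"))
  time <- factor(design$time, levels = c(1, 40))
  x_full <- stats::model.matrix(~ diet * time)
  x_add  <- stats::model.matrix(~ diet + time)
  resid_maker <- function(x) diag(n) - x %*% solve(crossprod(x), t(x))
  m_full <- resid_maker(x_full)
  m_add  <- resid_maker(x_add)
  sse_full <- rowSums((expr %*% m_full) * expr)
  sse_add  <- rowSums((expr %*% m_add) * expr)
  df2 <- n - 4L
  ms_within <- sse_full / df2
  f <- pmax(sse_add - sse_full, 0) / ms_within
  p <- stats::pf(f, 1, df2, lower.tail = FALSE)
  degen <- ms_within <= .Machine$double.eps * rowSums(expr^2)
  if (any(degen)) {
    warnf("%d gene(s) with zero within-cell variance: interaction p set to NA",
          sum(degen))
    f[degen] <- NA_real_; p[degen] <- NA_real_
  }
  data.frame(gene_id = rownames(expr),
             F_stat = f, p_value = p, q_value = bh_fdr(p),
             log2fc_1wk = timepoint_log2fc(expr, design, 1),
             log2fc_40wk = timepoint_log2fc(expr, design, 40),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap bookkeeping between the 1-week and 40-week screens
#'
#' Counts called genes per timepoint and direction, their share of the
#' tested transcript universe, and the genes called (in either direction)
#' at both timepoints.
#'
#' @param de_1wk,de_40wk DE tables from [de_per_timepoint()] over the same
#'   gene universe.
#' @return A list with counts `n_total_*`, `n_up_*`, `n_down_*` per
#'   timepoint, percentages `pct_1wk`/`pct_40wk` of the `universe_size`,
#'   `n_common`, and the sorted `common_genes` character vector.
#' @export
overlap_sets <- function(de_1wk, de_40wk) {
  if (!setequal(de_1wk$gene_id, de_40wk$gene_id))
    stopf("DE tables cover different gene universes")
  called <- function(d) d$gene_id[d$call != "ns"]
  n_up_1 <- sum(de_1wk$call == "up");  n_dn_1 <- sum(de_1wk$call == "down")
  n_up_40 <- sum(de_40wk$call == "up"); n_dn_40 <- sum(de_40wk$call == "down")
  common <- sort(intersect(called(de_1wk), called(de_40wk)))
  universe <- nrow(de_1wk)
  list(n_total_1wk = n_up_1 + n_dn_1, n_up_1wk = n_up_1, n_down_1wk = n_dn_1,
       n_total_40wk = n_up_40 + n_dn_40, n_up_40wk = n_up_40, n_down_40wk = n_dn_40,
       universe_size = universe,
       pct_1wk = 100 * (n_up_1 + n_dn_1) / universe,
       pct_40wk = 100 * (n_up_40 + n_dn_40) / universe,
       n_common = length(common), common_genes = common)
}

#' Select progressively induced genes
#'
#' Genes already moving at 1 week (`log2fc_1wk > fc1_min_log2`, i.e. fold
#' change > 1 by default) that become strongly induced at 40 weeks
#' (`log2fc_40wk > fc40_min_log2`, fold change > 2 by default) with a
#' significant diet x time interaction (`q <= q_max`). The fold-change
#' gates are strict inequalities.
#'
#' @param interaction Table from [interaction_test()].
#' @param q_max Interaction FDR ceiling (default 0.1).
#' @param fc1_min_log2 Strict lower bound on the 1-week log2 fold change
#'   (default 0, i.e. any induction).
#' @param fc40_min_log2 Strict lower bound on the 40-week log2 fold change
#'   (default 1, i.e. more than two-fold).
#' @return Character vector of selected gene IDs, in table order.
#' @export
select_progressive_genes <- function(interaction, q_max = 0.1,
                                     fc1_min_log2 = 0, fc40_min_log2 = 1) {
  keep <- !is.na(interaction$q_value) & interaction$q_value <= q_max &
    interaction$log2fc_1wk > fc1_min_log2 &
    interaction$log2fc_40wk > fc40_min_log2
  interaction$gene_id[keep]
}
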