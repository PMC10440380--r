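# Quantile normalization, log2 transform, BH, the Welch DE screen, the
# interaction ANOVA, overlap bookkeeping and progressive-gene selection.

test_that("quantile normalization matches the sorted-row-mean hand computation", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  rownames(m) <- paste0("g", 1:3)
  out <- quantile_normalize(m)
  expect_equal(unname(out[, "a"]), c(2.5, 3.5, 4.5), tolerance = 1e-12)
  expect_equal(unname(out[, "b"]), c(2.5, 3.5, 4.5), tolerance = 1e-12)

  # identical columns are left untouched
  m2 <- cbind(x = c(5, 1, 7), y = c(5, 1, 7))
  expect_equal(unname(quantile_normalize(m2)[, "x"]), c(5, 1, 7))

  # definitional postcondition on tie-free input: sorted columns equal
  set.seed(1)
  m3 <- matrix(runif(60, 0, 100), 10, 6)
  q3 <- quantile_normalize(m3)
  sorted <- apply(q3, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-9))
  # with ties, tied entries share the mean of the reference values at
  # their rank positions, so column sums still agree
  m4 <- cbind(c(1, 1, 5), c(2, 4, 6))
  q4 <- quantile_normalize(m4)
  expect_equal(sum(q4[, 1]), sum(q4[, 2]))
  expect_equal(q4[1, 1], q4[2, 1])

  expect_error(quantile_normalize(matrix(1:3, ncol = 1)), ">= 2 samples")
})

test_that("log2 transform applies the pseudocount and round-trips", {
  m <- matrix(c(0, 3, 7, 15), 2)
  out <- log2_transform(m, pseudocount = 1)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 2)
  expect_equal(as.vector(2^out - 1), as.vector(m), tolerance = 1e-12)
  expect_identical(attr(out, "expr_scale"), "log2")
  expect_error(log2_transform(m, pseudocount = 0), "positive")
  expect_error(log2_transform(m - 5), ">= 0")
})

test_that("BH correction follows the step-up formula and passes NAs through", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  q <- bh_fdr(c(0.01, NA, 0.04))
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], c(0.02, 0.04))  # m = 2 excludes the NA
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH equals an exhaustive step-up oracle for m <= 12", {
  oracle <- function(p) {
    m <- length(p)
    ord <- order(p)
    q_sorted <- pmin(1, p[ord] * m / seq_len(m))
    q_sorted <- rev(cummin(rev(q_sorted)))
    q <- numeric(m); q[ord] <- q_sorted
    q
  }
  set.seed(42)
  for (i in 1:25) {
    p <- round(runif(sample(1:12, 1)), 3)
    expect_equal(bh_fdr(p), oracle(p), tolerance = 1e-9)
  }
})

test_that("Welch DE screen reproduces the textbook t-test and calls", {
  design <- data.frame(
    sample_id = paste0("s", 1:8),
    diet = rep(c("LFD", "WD"), each = 4),
    time = 1L, sex = rep(c("F", "M"), 4), stringsAsFactors = FALSE)
  lfd <- c(1.0, 1.1, 0.9, 1.0); wd <- c(3.0, 3.1, 2.9, 3.0)
  expr <- rbind(g1 = c(lfd, wd))
  colnames(expr) <- design$sample_id
  tab <- de_per_timepoint(expr, design, time = 1)
  expect_equal(tab$log2fc, 2)
  expect_equal(tab$fold_change, 4)
  oracle <- t.test(wd, lfd)  # Welch by default
  expect_equal(tab$t_stat, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(tab$p_value, oracle$p.value, tolerance = 1e-9)
  expect_gt(tab$t_stat, 24)  # ~24.5
  expect_identical(tab$call, "up")
})

test_that("fold-change and FDR gates are inclusive and both mandatory", {
  design <- make_design(4)
  d1 <- design[design$time == 1, ]
  set.seed(2)
  # exactly representable values: WD = LFD + 1 gives log2fc exactly 1
  lfd_vals <- c(5, 5.0625, 4.9375, 5.125)
  base <- rbind(fc_2 = c(lfd_vals, lfd_vals + 1),
                fc_19 = c(lfd_vals, lfd_vals + log2(1.9)),
                null = rnorm(8, 5, 0.05))
  colnames(base) <- d1$sample_id[order(d1$diet)]
  wd <- d1$diet == "WD"
  tab <- de_per_timepoint(base, d1, 1)
  expect_identical(tab$fold_change[1], 2)
  expect_identical(tab$call[1], "up")
  expect_lt(tab$q_value[2], 0.001)
  expect_identical(tab$call[2], "ns")          # fc < 2: gate is mandatory
  # thresholds equal to the observed statistics still call (inclusive gates)
  tab_eq <- de_per_timepoint(base, d1, 1, fc_up = tab$fold_change[1],
                             fdr_max = tab$q_value[1])
  expect_identical(tab_eq$call[1], "up")
  # a gate just beyond the observed value stops the call (so it is the
  # inclusive comparison, not slack, that admitted it)
  tab_gt <- de_per_timepoint(base, d1, 1,
                             fc_up = tab$fold_change[1] * (1 + 1e-9))
  expect_identical(tab_gt$call[1], "ns")
})

test_that("zero-variance genes are reported NA/ns with a warning", {
  design <- make_design(3)
  d1 <- design[design$time == 1, ]
  expr <- rbind(flat = rep(2, nrow(d1)),
                ok = c(1, 1.2, 0.8, 3.1, 2.9, 3.0))
  colnames(expr) <- d1$sample_id
  expect_warning(tab <- de_per_timepoint(expr, d1, 1), "zero within-group")
  expect_true(is.na(tab$p_value[1]))
  expect_identical(tab$call[1], "ns")
  expect_false(is.na(tab$q_value[2]))
})

test_that("interaction F matches the hand ANOVA decomposition and stats::aov", {
  design <- data.frame(sample_id = paste0("s", 1:8),
                       diet = rep(c("LFD", "WD", "LFD", "WD"), each = 2),
                       time = rep(c(1L, 40L), each = 4),
                       sex = "F", stringsAsFactors = FALSE)
  expr <- rbind(g1 = c(1, 2, 1, 2, 1, 2, 5, 6))
  colnames(expr) <- design$sample_id
  it <- interaction_test(expr, design)
  expect_equal(it$F_stat, 16, tolerance = 1e-9)   # SS_int = 8, MS_within = 0.5
  expect_equal(it$p_value, pf(16, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(it$log2fc_40wk, 4)

  # unbalanced design: agree with the aov interaction row to 1e-9
  set.seed(3)
  design2 <- make_design(3)
  design2 <- design2[-1, ]  # drop one LFD-1wk sample -> unbalanced
  y <- matrix(rnorm(5 * nrow(design2)), 5, nrow(design2),
              dimnames = list(paste0("g", 1:5), design2$sample_id))
  it2 <- interaction_test(y, design2)
  for (g in 1:5) {
    fit <- stats::aov(y[g, ] ~ factor(design2$diet) * factor(design2$time))
    a <- summary(fit)[[1]]
    expect_equal(it2$F_stat[g], a["factor(design2$diet):factor(design2$time)", "F value"],
                 tolerance = 1e-9)
  }
})

test_that("interaction F equals the squared contrast t on balanced designs", {
  set.seed(4)
  design <- make_design(4)
  y <- matrix(rnorm(20 * nrow(design)), 20, nrow(design),
              dimnames = list(paste0("g", 1:20), design$sample_id))
  it <- interaction_test(y, design)
  grp <- wdliver:::design_groups(design)
  for (g in 1:20) {
    cells <- split(y[g, ], grp)
    n <- lengths(cells)
    est <- (mean(cells[["WD-40wk"]]) - mean(cells[["LFD-40wk"]])) -
      (mean(cells[["WD-1wk"]]) - mean(cells[["LFD-1wk"]]))
    s2 <- sum(vapply(cells, function(v) sum((v - mean(v))^2), 1)) / (sum(n) - 4)
    tstat <- est / sqrt(s2 * sum(1 / n))
    expect_equal(it$F_stat[g], tstat^2, tolerance = 1e-9)
  }
})

test_that("interaction p-values are uniform under a pure main-effects null", {
  set.seed(5)
  design <- make_design(6)
  y <- make_gaussian_expr(design, 2000, sd = 0.5)
  # add main effects only: diet +1, time +0.5 (no interaction)
  y <- y + outer(rep(1, 2000), as.numeric(design$diet == "WD")) +
    outer(rep(0.5, 2000), as.numeric(design$time == 40))
  it <- interaction_test(y, design)
  ks <- suppressWarnings(stats::ks.test(it$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("overlap bookkeeping counts directions and the common set", {
  mk <- function(ids, calls) data.frame(gene_id = ids, call = calls,
                                        stringsAsFactors = FALSE)
  ids <- c("A", "B", "C", "D")
  d1 <- mk(ids, c("up", "down", "ns", "ns"))
  d40 <- mk(ids, c("ns", "down", "up", "ns"))
  ov <- overlap_sets(d1, d40)
  expect_equal(ov$n_total_1wk, 2)
  expect_equal(ov$n_common, 1)
  expect_identical(ov$common_genes, "B")
  expect_equal(ov$n_total_1wk, ov$n_up_1wk + ov$n_down_1wk)
  expect_equal(ov$n_total_40wk, ov$n_up_40wk + ov$n_down_40wk)

  none <- mk(ids, rep("ns", 4))
  ov0 <- overlap_sets(none, none)
  expect_equal(ov0$n_total_1wk + ov0$n_total_40wk + ov0$n_common, 0)

  expect_error(overlap_sets(d1, mk(c("X", "Y", "Z", "W"), rep("ns", 4))),
               "universes")
})

test_that("progressive-gene selection applies strict fold-change gates", {
  tab <- data.frame(
    gene_id = c("sel", "neg1wk", "weak40", "exact0", "na_q"),
    q_value = c(0.05, 0.01, 0.01, 0.01, NA),
    log2fc_1wk = c(0.5, -0.2, 0.5, 0, 1),
    log2fc_40wk = c(log2(3), 2, log2(1.5), 2, 2),
    stringsAsFactors = FALSE)
  expect_identical(select_progressive_genes(tab), "sel")
  # boundary log2fc_40wk exactly 1 (fold change exactly 2) is excluded
  tab$log2fc_40wk[1] <- 1
  expect_identical(select_progressive_genes(tab), character(0))
})

test_that("fold-change gating and BH order-independence on a fixed universe", {
  set.seed(6)
  sim <- simulate_bulk_counts(bulk_sim_config(n_genes = 400, seed = 10))
  lg <- log2_transform(quantile_normalize(sim$counts))
  tab <- de_per_timepoint(lg, sim$design, 40)
  # BH on all tested genes, then gates - must equal the table's call set
  q <- bh_fdr(tab$p_value)
  manual_up <- tab$gene_id[!is.na(q) & q <= 0.1 & tab$fold_change >= 2]
  expect_setequal(manual_up, tab$gene_id[tab$call == "up"])
})
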