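## Enrichment: hypergeometric over-representation against GMT gene sets,
## preranked GSEA with a gene-label permutation null, and the
## qRT-PCR/RNA-seq concordance statistic.

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric tail `P(X >= k)` per gene set, with
#' `N = |background|`, `K = |set intersected with background|`,
#' `n = |query|`, `k = |set intersected with query|`; BH correction across
#' the tested sets.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `background`.
#' @param sets Named list of gene-ID vectors (see [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @return A data.frame per set: `set_name`, `set_size` (in background),
#'   `n_overlap`, `p_value`, `q_value`, ordered by p. Sets disjoint from
#'   the background are skipped with a warning.
#' @export
hypergeometric_ora <- function(query, sets, background) {
  query <- unique(query); background <- unique(background)
  if (length(background) == 0) stopf("empty background")
  if (length(query) == 0) stopf("empty query")
  if (!all(query %in% background))
    stopf("query must be a subset of the background (%d gene(s) outside)",
          sum(!query %in% background))
  ok_sets <- lapply(sets, intersect, background)
  empty <- lengths(ok_sets) == 0
  if (any(empty)) {
    warnf("skipping %d set(s) with no background genes: %s",
          sum(empty), paste(names(sets)[empty], collapse = ", "))
    ok_sets <- ok_sets[!empty]
  }
  if (length(ok_sets) == 0) stopf("no testable gene sets")
  N <- length(background); n <- length(query)
  K <- lengths(ok_sets)
  k <- vapply(ok_sets, function(s) length(intersect(s, query)), integer(1))
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(set_name = names(ok_sets), set_size = unname(K),
                    n_overlap = unname(k), p_value = unname(p),
                    q_value = bh_fdr(unname(p)),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_value, out$set_name), , drop = FALSE]
}

# Running-sum enrichment score for one set over a ranked score vector.
# hit increments carry |score|^weight mass, misses -1/(N-K).
gsea_es <- function(in_set, scores, weight) {
  N <- length(scores); K <- sum(in_set)
  if (K == 0 || K == N)
    stopf("gene set must hit a strict, non-empty subset of the ranked list")
  w <- abs(scores)^weight
  hit_mass <- sum(w[in_set])
  step <- ifelse(in_set,
                 if (hit_mass > 0) w / hit_mass else 1 / K,
                 -1 / (N - K))
  running <- cumsum(step)
  running[which.max(abs(running))]
}

#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running sum over a
#' descending-ranked gene list: in-set genes add `|score|^weight`
#' normalized over the in-set mass, misses subtract `1/(N-K)`; the
#' enrichment score (ES) is the extremum of largest magnitude. Significance
#' comes from `n_perm` gene-label permutations: the p-value is the
#' fraction of same-sign permutation ES values at least as extreme
#' (add-one smoothed), and `NES = ES / mean(|ES_perm|)` over the same-sign
#' permutations. BH correction across sets.
#'
#' @param ranked Named numeric vector of scores (names are unique gene
#'   IDs), sorted in descending order; the default ranking metric upstream
#'   is the log2 fold change.
#' @param sets Named list of gene-ID vectors.
#' @param weight Score weighting exponent (default 1; 0 gives the
#'   unweighted KS form).
#' @param n_perm Number of permutations (default 1000).
#' @param min_size Minimum in-list set size (default 3); smaller sets are
#'   dropped with a warning.
#' @param seed Integer seed for the permutations.
#' @return A data.frame per set: `set_name`, `n_overlap`, `es`, `nes`,
#'   `p_value`, `q_value`, `n_perm_used`, ordered by p.
#' @export
gsea_preranked <- function(ranked, sets, weight = 1, n_perm = 1000,
                           min_size = 3, seed = 1) {
  if (is.null(names(ranked)) || anyDuplicated(names(ranked)))
    stopf("ranked must be a named vector with unique gene IDs")
  if (is.unsorted(rev(ranked)))
    stopf("ranked scores must be sorted in descending order")
  genes <- names(ranked)
  sizes <- vapply(sets, function(s) sum(genes %in% s), integer(1))
  drop <- sizes < min_size | sizes >= length(genes)
  if (all(drop)) stopf("no gene set within the size bounds")
  if (any(drop))
    warnf("dropping %d set(s) outside size bounds: %s", sum(drop),
          paste(names(sets)[drop], collapse = ", "))
  sets <- sets[!drop]; sizes <- sizes[!drop]

  res <- withr::with_seed(seed, {
    lapply(names(sets), function(nm) {
      in_set <- genes %in% sets[[nm]]
      es <- gsea_es(in_set, ranked, weight)
      K <- sum(in_set)
      perm <- vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(length(genes), K)
        gsea_es(seq_along(genes) %in% idx, ranked, weight)
      }, numeric(1))
      same <- perm[sign(perm) == sign(es)]
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      nes <- if (length(same)) es / mean(abs(same)) else NA_real_
      data.frame(set_name = nm, n_overlap = K, es = es, nes = nes,
                 p_value = p, n_perm_used = n_perm,
                 row.names = NULL, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, res)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name),
             c("set_name", "n_overlap", "es", "nes", "p_value", "q_value",
               "n_perm_used")]
  rownames(out) <- NULL
  out
}

#' qRT-PCR / RNA-seq concordance
#'
#' Pearson correlation on the paired (log-scale) expression values and
#' Spearman correlation on their ranks, each with a two-sided p-value.
#'
#' @param x,y Paired numeric vectors (same genes, length >= 3), already on
#'   a comparable log scale.
#' @return A list: `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `n`.
#' @export
concordance <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must be paired (equal length)")
  if (length(x) < 3) stopf("need at least 3 pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stopf("zero variance in x or y")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}
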