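## Assignment of bulk genes to cell types via marker-catalog membership,
## and the per-type percentage summary.

#' Assign bulk genes to cell types
#'
#' A queried gene is assigned to the cell type whose marker catalog
#' contains it; genes in no marker set are `"unassigned"`. With a
#' non-unique catalog, a gene appearing under several types is resolved by
#' highest `log2fc_vs_rest`, then lexicographic type name (a message
#' reports how many ties were broken). Genes absent from the single-cell
#' gene universe get reason `"not_measured"` rather than being dropped.
#'
#' @param genes Character vector of gene IDs to assign (e.g. the
#'   interaction gene set).
#' @param catalog A `marker_catalog` from [derive_markers()].
#' @return A data.frame with one row per queried gene: `gene_id`,
#'   `cell_type` (or `"unassigned"`), `reason` (`"marker"`,
#'   `"not_marker"`, `"not_measured"`).
#' @export
assign_genes <- function(genes, catalog) {
  if (nrow(catalog) == 0) stopf("marker catalog is empty")
  if (anyDuplicated(genes)) stopf("queried gene list contains duplicates")
  cat <- as.data.frame(catalog)
  if (!isTRUE(attr(catalog, "unique")) && anyDuplicated(cat$gene_id)) {
    n_tied <- length(unique(cat$gene_id[duplicated(cat$gene_id)]))
    message(sprintf("resolving %d multi-type gene(s) by log2fc then type name",
                    n_tied))
    cat <- cat[order(cat$gene_id, -cat$log2fc_vs_rest, cat$cell_type), ]
    cat <- cat[!duplicated(cat$gene_id), ]
  }
  owner <- stats::setNames(cat$cell_type, cat$gene_id)
  universe <- attr(catalog, "gene_universe") %||% cat$gene_id
  cell_type <- unname(owner[genes])
  reason <- ifelse(!is.na(cell_type), "marker",
                   ifelse(genes %in% universe, "not_marker", "not_measured"))
  cell_type[is.na(cell_type)] <- "unassigned"
  data.frame(gene_id = genes, cell_type = cell_type, reason = reason,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarize a cell-type assignment
#'
#' Counts and percentages per cell type, ordered by descending count. The
#' percentage denominator is either every queried gene (`"queried"`, the
#' default) or only the genes that received a type (`"assigned"`).
#'
#' @param assignment Data.frame from [assign_genes()].
#' @param denominator `"queried"` or `"assigned"`.
#' @return A data.frame `cell_type`, `n_genes`, `pct`; the `"unassigned"`
#'   row is included (pct 0 under the `"assigned"` denominator). Attribute
#'   `n_unassigned` carries the unassigned count.
#' @export
assignment_summary <- function(assignment, denominator = c("queried", "assigned")) {
  denominator <- match.arg(denominator)
  if (nrow(assignment) == 0) stopf("empty assignment")
  counts <- table(assignment$cell_type)
  n_unassigned <- sum(assignment$cell_type == "unassigned")
  denom <- switch(denominator,
                  queried = nrow(assignment),
                  assigned = nrow(assignment) - n_unassigned)
  out <- data.frame(cell_type = names(counts),
                    n_genes = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$pct <- if (denom > 0) 100 * out$n_genes / denom else 0
  if (denominator == "assigned" && n_unassigned > 0)
    out$pct[out$cell_type == "unassigned"] <- 0
  out <- out[order(-out$n_genes, out$cell_type), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- n_unassigned
  attr(out, "denominator") <- denominator
  out
}
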