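## Internal helpers shared across modules.

#' @importFrom stats pf pt pnorm phyper median var sd rnbinom rnorm runif
#'   rpois rlnorm setNames quantile p.adjust complete.cases prcomp kmeans
#'   cor.test wilcox.test
#' @importFrom utils read.delim write.table head
NULL

# Tab-delimited writer used for every text output: UTF-8, '.' decimal,
# header row, no quoting. Full-precision numbers survive a read round trip.
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = FALSE, trim = TRUE)
    }, character(1))
    out
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == round(x) && x > 0

# Matrix scale tag ("normalized", "log2", "cpm") carried as an attribute.
set_scale <- function(x, scale) { attr(x, "expr_scale") <- scale; x }
get_scale <- function(x) attr(x, "expr_scale") %||% "unknown"

`%||%` <- function(a, b) if (is.null(a)) b else a

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# Group labels "LFD-1wk", "WD-1wk", "LFD-40wk", "WD-40wk" in fixed order.
GROUP_LEVELS <- c("LFD-1wk", "WD-1wk", "LFD-40wk", "WD-40wk")

design_groups <- function(design) {
  factor(paste0(design$diet, "-", design$time, "wk"), levels = GROUP_LEVELS)
}
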