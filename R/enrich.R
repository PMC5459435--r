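#' Upper-tail hypergeometric enrichment p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing n genes (the
#' affected set) from a universe of N of which K belong to the query set.
#'
#' @param k Observed overlap.
#' @param K Query-set size.
#' @param n Drawn (affected) set size.
#' @param N Universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_test <- function(k, K, n, N) {
  vals <- c(k = k, K = K, n = n, N = N)
  if (any(is.na(vals)) || any(vals < 0) ||
      any(abs(vals - round(vals)) > 1e-8)) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (k > min(K, n) || K > N || n > N) {
    stop("inconsistent counts: need k <= min(K, n) and K, n <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Sums, over the margin-fixed table set, the hypergeometric probabilities
#' not exceeding that of the observed table. Degenerate tables (a zero
#' margin, or all zeros) return 1 by convention.
#'
#' @param a,b,c,d Non-negative integer cells, row-wise: table
#'   \code{rbind(c(a, b), c(c, d))}.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) ||
      any(abs(cells - round(cells)) > 1e-8)) {
    stop("table cells must be non-negative integers")
  }
  if (sum(cells) == 0) return(1)
  tab <- matrix(as.integer(round(cells)), nrow = 2, byrow = TRUE)
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; monotone in the p-value ranks and capped at 1.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set overlap and enrichment report
#'
#' For each query set: the overlap k with the affected genes, the set size
#' K, the overlap fraction k/K, an upper-tail hypergeometric enrichment
#' p-value against a universe of N genes, and the Benjamini-Hochberg
#' q-value across all sets in the report.
#'
#' @param affected_genes Character vector of affected gene ids.
#' @param gene_sets Named list of gene-id vectors.
#' @param universe Either the universe size (single number) or a character
#'   vector of universe gene ids. When ids are given, set members outside
#'   the universe trigger a warning and are dropped.
#' @return data.frame: set, k, K, n, N, fraction, p_value, q_value.
#' @export
overlap_report <- function(affected_genes, gene_sets, universe) {
  affected <- unique(affected_genes)
  if (is.numeric(universe) && length(universe) == 1L) {
    N <- as.integer(universe)
    universe_ids <- NULL
  } else {
    universe_ids <- unique(as.character(universe))
    N <- length(universe_ids)
  }
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("`gene_sets` must be a named list")
  }
  n <- length(affected)
  if (n > N) stop("affected set is larger than the universe")
  rows <- lapply(names(gene_sets), function(nm) {
    set <- unique(as.character(gene_sets[[nm]]))
    if (!is.null(universe_ids)) {
      out_of <- setdiff(set, universe_ids)
      if (length(out_of)) {
        warning(sprintf("set '%s': %d id(s) outside the universe dropped",
                        nm, length(out_of)))
        set <- intersect(set, universe_ids)
      }
    }
    K <- length(set)
    if (K > N) stop(sprintf("set '%s' is larger than the universe", nm))
    k <- length(intersect(affected, set))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               fraction = if (K > 0) k / K else NA_real_,
               p_value = hypergeom_test(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  rownames(out) <- NULL
  out
}
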