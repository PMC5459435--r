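#' Per-library size factors
#'
#' Geometric-mean-centered scaling factors, so that the product of the
#' factors is 1 and dividing each library's counts by its factor puts all
#' libraries on a common scale.
#'
#' @param library_totals Positive numeric vector of library sizes (method
#'   `"library_total"`), or a matrix of window counts with one column per
#'   library (method `"geometric"`, DESeq-style median-of-ratios).
#' @param method Size-factor method.
#' @return Numeric vector of positive factors with product 1.
#' @export
estimate_size_factors <- function(library_totals,
                                  method = c("library_total", "geometric")) {
  method <- match.arg(method)
  if (method == "library_total") {
    totals <- as.numeric(library_totals)
    if (any(is.na(totals)) || any(totals <= 0)) {
      stop("all library totals must be positive")
    }
    gm <- exp(mean(log(totals)))
    return(totals / gm)
  }
  counts <- as.matrix(library_totals)
  if (any(counts < 0)) stop("counts must be non-negative")
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) stop("no window has positive counts in every library")
  logref <- rowMeans(log(counts[keep, , drop = FALSE]))
  f <- apply(counts[keep, , drop = FALSE], 2,
             function(x) exp(stats::median(log(x) - logref)))
  f / exp(mean(log(f)))
}

# Conditional two-sided exact p-value for one adjusted count pair.
# Given total t, the conditional distribution of the first count under the
# null of equal means is binomial(t, 1/2) for phi = 0 and the symmetric
# negative-binomial conditional (a beta-binomial form that does not depend
# on the mean) for phi > 0. Two-sided p sums all outcome probabilities not
# exceeding that of the observed outcome.
.exact_test_one <- function(a, b, phi) {
  t <- a + b
  if (t == 0L) return(1)
  k <- 0:t
  if (phi == 0) {
    logp <- stats::dbinom(k, t, 0.5, log = TRUE)
  } else {
    r <- 1 / phi
    logp <- lchoose(k + r - 1, k) + lchoose(t - k + r - 1, t - k)
    logp <- logp - max(logp)
    logp <- logp - log(sum(exp(logp)))
  }
  p_obs <- logp[a + 1L]
  min(1, sum(exp(logp[logp <= p_obs + 1e-7])))
}

#' No-replicate negative-binomial exact test for one window
#'
#' Conditional two-sided exact test between two libraries without
#' replicates. Counts are first adjusted to a common library scale by
#' dividing by their size factors and rounding to the nearest integer;
#' conditioned on the adjusted total, the two-sided p-value sums the
#' probabilities of all outcomes no more likely than the observed one.
#' With dispersion 0 the conditional distribution is binomial(t, 1/2)
#' (the Poisson case); with dispersion phi > 0 it is the symmetric
#' negative-binomial conditional with size 1/phi, which does not depend
#' on the unknown mean.
#'
#' @param count_a,count_b Non-negative integer counts (control, case).
#' @param factor_a,factor_b Positive size factors (see
#'   [estimate_size_factors()]).
#' @param dispersion Negative-binomial dispersion phi >= 0 (variance =
#'   mu + phi mu^2); 0 gives the Poisson/binomial conditional test.
#' @return Two-sided p-value in (0, 1]. Both counts zero returns 1 by
#'   convention.
#' @examples
#' nb_exact_test(0, 10, dispersion = 0)  # 2 * (1/2)^10
#' @export
nb_exact_test <- function(count_a, count_b, factor_a = 1, factor_b = 1,
                          dispersion = 0.1) {
  if (length(count_a) != 1L || length(count_b) != 1L) {
    stop("`nb_exact_test` is scalar; use `call_dhmrs` for tracks")
  }
  if (is.na(count_a) || is.na(count_b) ||
      abs(count_a - round(count_a)) > 1e-8 ||
      abs(count_b - round(count_b)) > 1e-8 || count_a < 0 || count_b < 0) {
    stop("counts must be non-negative integers")
  }
  if (factor_a <= 0 || factor_b <= 0) stop("size factors must be positive")
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  a <- as.integer(round(count_a / factor_a))
  b <- as.integer(round(count_b / factor_b))
  .exact_test_one(a, b, dispersion)
}

#' Exact-test parameters for DhMR calling
#'
#' @param dispersion Assumed negative-binomial dispersion phi (default
#'   0.1); a no-replicate design cannot estimate it from the data, so it
#'   is an explicit modeling choice. 0 gives the Poisson exact test.
#' @param p_threshold Raw p-value threshold for calling (default 0.005).
#' @param min_total_count Minimum adjusted total count for a window to be
#'   tested (default 1).
#' @param size_factor_method `"library_total"` or `"geometric"`.
#' @return A `dhmr_params` list.
#' @export
dhmr_params <- function(dispersion = 0.1, p_threshold = 0.005,
                        min_total_count = 1L,
                        size_factor_method = c("library_total", "geometric")) {
  if (dispersion < 0) stop("`dispersion` must be >= 0")
  if (p_threshold <= 0 || p_threshold > 1) {
    stop("`p_threshold` must be in (0, 1]")
  }
  structure(list(dispersion = dispersion, p_threshold = p_threshold,
                 min_total_count = as.integer(min_total_count),
                 size_factor_method = match.arg(size_factor_method)),
            class = "dhmr_params")
}

#' Call differentially hydroxymethylated windows
#'
#' Tests every window whose adjusted total count reaches
#' `min_total_count` with the conditional exact test and returns the
#' windows at or below the raw p-value threshold, classified hyper
#' (normalized case rate above control) or hypo. Windows whose adjusted
#' counts tie are never called (no direction). A Benjamini-Hochberg FDR
#' column over all tested windows is attached for transparency but is not
#' used for calling; adjacent significant windows are not merged unless
#' `merge = TRUE`.
#'
#' @param counts_control,counts_case `window_counts` on the same grid.
#' @param grid Window grid.
#' @param params `dhmr_params` object.
#' @param merge Merge adjacent same-direction significant windows into
#'   regions (default FALSE: window-level records).
#' @return data.frame of DhMRs (chrom, start, end, count_control,
#'   count_case, rpkm_control, rpkm_case, p_value, fdr, direction) with
#'   attributes `n_tested` (windows tested) and `size_factors`.
#' @export
call_dhmrs <- function(counts_control, counts_case, grid,
                       params = dhmr_params(), merge = FALSE) {
  stopifnot(inherits(counts_control, "window_counts"),
            inherits(counts_case, "window_counts"),
            inherits(params, "dhmr_params"))
  n <- length(grid)
  if (length(counts_control$counts) != n || length(counts_case$counts) != n) {
    stop("count tracks and grid have different numbers of windows")
  }
  if (params$size_factor_method == "library_total") {
    sf <- estimate_size_factors(c(counts_control$library_total,
                                  counts_case$library_total))
  } else {
    sf <- estimate_size_factors(cbind(counts_control$counts,
                                      counts_case$counts),
                                method = "geometric")
  }
  adj_a <- as.integer(round(counts_control$counts / sf[1]))
  adj_b <- as.integer(round(counts_case$counts / sf[2]))
  tested <- which(adj_a + adj_b >= params$min_total_count)
  # memoize on unique adjusted pairs
  key <- paste(adj_a[tested], adj_b[tested])
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i) {
    .exact_test_one(adj_a[tested[i]], adj_b[tested[i]], params$dispersion)
  }, numeric(1))
  p <- unname(pu[match(key, key[uk])])
  fdr <- stats::p.adjust(p, method = "BH")
  sig <- p <= params$p_threshold & adj_a[tested] != adj_b[tested]
  idx <- tested[sig]
  rpkm_c <- to_rpkm(counts_control, grid)
  rpkm_e <- to_rpkm(counts_case, grid)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(grid[idx])),
    start = GenomicRanges::start(grid[idx]),
    end = GenomicRanges::end(grid[idx]),
    count_control = counts_control$counts[idx],
    count_case = counts_case$counts[idx],
    rpkm_control = rpkm_c$rpkm[idx],
    rpkm_case = rpkm_e$rpkm[idx],
    p_value = p[sig],
    fdr = fdr[sig],
    direction = ifelse(adj_b[idx] > adj_a[idx], "hyper", "hypo"),
    stringsAsFactors = FALSE)
  if (merge && nrow(out) > 0) {
    out <- .merge_dhmrs(out)
  }
  attr(out, "n_tested") <- length(tested)
  attr(out, "size_factors") <- sf
  out
}

# Collapse runs of adjacent significant windows with the same direction.
.merge_dhmrs <- function(dhmrs) {
  gr <- GenomicRanges::GRanges(dhmrs$chrom,
                               IRanges::IRanges(dhmrs$start, dhmrs$end),
                               direction = dhmrs$direction)
  out <- lapply(c("hyper", "hypo"), function(d) {
    sub <- gr[gr$direction == d]
    if (length(sub) == 0L) return(NULL)
    red <- GenomicRanges::reduce(sub)
    ov <- GenomicRanges::findOverlaps(red, sub)
    best_p <- tapply(dhmrs$p_value[dhmrs$direction == d][S4Vectors::subjectHits(ov)],
                     S4Vectors::queryHits(ov), min)
    data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
               start = GenomicRanges::start(red),
               end = GenomicRanges::end(red),
               n_windows = as.integer(table(S4Vectors::queryHits(ov))),
               p_value = as.numeric(best_p),
               direction = d, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' DhMR table as GRanges
#'
#' @param dhmrs data.frame from [call_dhmrs()].
#' @return `GRanges` with the remaining columns as metadata.
#' @export
dhmrs_as_granges <- function(dhmrs) {
  if (nrow(dhmrs) == 0L) {
    gr <- GenomicRanges::GRanges()
    gr$direction <- character(0)
    return(gr)
  }
  gr <- GenomicRanges::GRanges(dhmrs$chrom,
                               IRanges::IRanges(dhmrs$start, dhmrs$end))
  S4Vectors::mcols(gr) <- dhmrs[, setdiff(names(dhmrs),
                                          c("chrom", "start", "end")),
                                drop = FALSE]
  gr
}
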