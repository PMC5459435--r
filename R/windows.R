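#' Partition a genome into fixed-width windows
#'
#' Builds the window grid every count, RPKM and coverage statistic in the
#' package is indexed on. Windows tile each chromosome exactly once; the
#' final window of a chromosome is truncated at the chromosome end.
#'
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param width Window width in bp; the pipeline default is 100.
#' @return A `GRanges` tiling of the genome with `seqlengths` set. The
#'   window width is stored in `metadata()$window_width`.
#' @examples
#' grid <- make_windows(c(chr1 = 1050), width = 100)
#' length(grid)  # 11 windows, last one 50 bp
#' @export
make_windows <- function(chrom_sizes, width = 100L) {
  chrom_sizes <- .check_chrom_sizes(chrom_sizes)
  if (length(width) != 1L || is.na(width) || width <= 0) {
    stop("`width` must be a single positive number of base pairs")
  }
  si <- GenomeInfoDb::Seqinfo(names(chrom_sizes), unname(chrom_sizes))
  grid <- GenomicRanges::tileGenome(si, tilewidth = as.integer(width),
                                    cut.last.tile.in.chrom = TRUE)
  S4Vectors::metadata(grid)$window_width <- as.integer(width)
  grid
}

#' Count reads per window
#'
#' Overlap counting: a read increments every window it overlaps by at least
#' one base, so the column sum can exceed the number of reads. The library
#' total kept for normalization is the number of input reads, not the sum
#' of window counts.
#'
#' @param grid Window grid from [make_windows()].
#' @param reads `GRanges` of aligned reads or BED path (see
#'   [as_read_granges()]).
#' @param mapq_min Optional mapping-quality filter applied at input.
#' @return A `window_counts` object: list with integer `counts` parallel to
#'   `grid` and `library_total`.
#' @export
count_reads <- function(grid, reads, mapq_min = NULL) {
  reads <- as_read_granges(reads, mapq_min = mapq_min)
  reads <- .match_seqlevels(reads, grid, "reads")
  counts <- GenomicRanges::countOverlaps(grid, reads, ignore.strand = TRUE)
  structure(list(counts = as.integer(counts),
                 library_total = length(reads)),
            class = "window_counts")
}

#' @export
print.window_counts <- function(x, ...) {
  cat(sprintf("<window_counts> %d windows, %d reads, %d windows covered\n",
              length(x$counts), x$library_total, sum(x$counts > 0L)))
  invisible(x)
}

#' Transform window counts to RPKM
#'
#' RPKM = count / (window length in kb \eqn{\times} library size in
#' millions), using each window's actual length (the final window of a
#' chromosome can be shorter than the grid width).
#'
#' @param track `window_counts` from [count_reads()].
#' @param grid The grid the counts were computed on.
#' @return A `window_rpkm` object: list with numeric `rpkm` parallel to the
#'   grid and `library_total`.
#' @export
to_rpkm <- function(track, grid) {
  stopifnot(inherits(track, "window_counts"))
  if (length(track$counts) != length(grid)) {
    stop("count track and grid have different numbers of windows")
  }
  if (track$library_total <= 0L) {
    stop("library_total is zero: RPKM normalization is undefined")
  }
  kb <- GenomicRanges::width(grid) / 1000
  per_million <- track$library_total / 1e6
  structure(list(rpkm = track$counts / (kb * per_million),
                 library_total = track$library_total),
            class = "window_rpkm")
}

#' Identify covered windows
#'
#' A window is covered if any part of it is overlapped by at least one
#' sequencing read, i.e. its overlap count is >= 1.
#'
#' @param track `window_counts`.
#' @return A `covered_windows` object: list with integer window indices
#'   `idx`, `n_windows` and covered `fraction`.
#' @export
covered_windows <- function(track) {
  stopifnot(inherits(track, "window_counts"))
  idx <- which(track$counts >= 1L)
  structure(list(idx = idx,
                 n_windows = length(track$counts),
                 fraction = length(idx) / length(track$counts)),
            class = "covered_windows")
}

#' Covered windows as merged genomic regions
#'
#' @param covered `covered_windows` object.
#' @param grid The matching window grid.
#' @return Reduced `GRanges` of covered bases.
#' @export
covered_regions <- function(covered, grid) {
  stopifnot(inherits(covered, "covered_windows"))
  if (covered$n_windows != length(grid)) {
    stop("covered set and grid have different numbers of windows")
  }
  GenomicRanges::reduce(grid[covered$idx])
}

# Accept either a covered_windows object (+grid) or a plain GRanges of
# covered regions.
.as_covered_regions <- function(covered, grid = NULL) {
  if (inherits(covered, "covered_windows")) {
    if (is.null(grid)) stop("`grid` is required with a covered_windows object")
    return(covered_regions(covered, grid))
  }
  if (methods::is(covered, "GRanges")) {
    return(GenomicRanges::reduce(covered))
  }
  stop("`covered` must be a covered_windows object or a GRanges")
}

#' Sequencing-saturation analysis
#'
#' Estimates whether sequencing depth suffices for reproducible windowed
#' coverage. Reads are split at random into two halves A and B; for
#' k = 1..steps the Pearson correlation between the window counts of the
#' first k/steps fraction of A and all of B is computed (the "truncated"
#' curve, whose last point uses half the data on each side). The headline
#' "estimated" saturation doubles each half by bootstrap resampling before
#' the final correlation, extrapolating to a library of the full input
#' size on both sides.
#'
#' @param reads Reads (`GRanges` or BED path).
#' @param grid Window grid.
#' @param steps Number of subset fractions (default 10).
#' @param seed Optional integer seed for the random split.
#' @return List with `curve` (data.frame: fraction, n_reads, correlation),
#'   `truncated` (correlation at the full half-vs-half step) and
#'   `estimated` (doubled-set extrapolation; the headline number).
#' @export
saturation_analysis <- function(reads, grid, steps = 10L, seed = NULL) {
  reads <- as_read_granges(reads)
  n <- length(reads)
  if (n < 2L) stop("saturation analysis requires at least 2 reads")
  if (steps < 1L) stop("`steps` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  perm <- sample.int(n)
  half <- n %/% 2L
  a <- reads[perm[seq_len(half)]]
  b <- reads[perm[(half + 1L):n]]
  counts_b <- GenomicRanges::countOverlaps(grid, b, ignore.strand = TRUE)
  fractions <- seq_len(steps) / steps
  n_sub <- pmax(1L, floor(fractions * length(a)))
  cors <- vapply(n_sub, function(k) {
    ca <- GenomicRanges::countOverlaps(grid, a[seq_len(k)],
                                       ignore.strand = TRUE)
    stats::cor(ca, counts_b)
  }, numeric(1))
  a2 <- c(a, a[sample.int(length(a), length(a), replace = TRUE)])
  b2 <- c(b, b[sample.int(length(b), length(b), replace = TRUE)])
  estimated <- stats::cor(
    GenomicRanges::countOverlaps(grid, a2, ignore.strand = TRUE),
    GenomicRanges::countOverlaps(grid, b2, ignore.strand = TRUE))
  list(curve = data.frame(fraction = fractions, n_reads = n_sub,
                          correlation = cors),
       truncated = cors[steps],
       estimated = estimated)
}

#' CpG enrichment score of an immunoprecipitated library
#'
#' Ratio of CpG density within read-covered bases to genome-wide CpG
#' density. A score of 1 means no enrichment; successful (hydroxy)methyl
#' enrichment yields scores above 1. CpG sites are represented by the
#' coordinate of the C on the forward strand, so each palindromic CpG is
#' counted once.
#'
#' @param reads Reads (`GRanges` or BED path).
#' @param cpg_positions `GRanges` of CpG sites (width-1, C position).
#' @param chrom_sizes Named vector of chromosome lengths.
#' @return Single numeric enrichment score.
#' @export
cpg_enrichment_score <- function(reads, cpg_positions, chrom_sizes) {
  reads <- as_read_granges(reads)
  if (length(reads) == 0L) stop("CpG enrichment is undefined with zero reads")
  if (length(cpg_positions) == 0L) {
    stop("CpG enrichment is undefined with zero CpG sites")
  }
  chrom_sizes <- .check_chrom_sizes(chrom_sizes)
  covered <- GenomicRanges::reduce(reads, ignore.strand = TRUE)
  covered_bases <- sum(as.numeric(GenomicRanges::width(covered)))
  genome_bases <- sum(as.numeric(chrom_sizes))
  n_in <- sum(GenomicRanges::countOverlaps(cpg_positions, covered,
                                           ignore.strand = TRUE) > 0L)
  (n_in / covered_bases) / (length(cpg_positions) / genome_bases)
}

#' Fraction of CpG sites with at least 1x read coverage
#'
#' @param reads Reads (`GRanges` or BED path).
#' @param cpg_positions `GRanges` of CpG sites.
#' @return Fraction in \[0, 1\].
#' @export
cpg_coverage_fraction <- function(reads, cpg_positions) {
  reads <- as_read_granges(reads)
  if (length(cpg_positions) == 0L) return(NA_real_)
  covered <- GenomicRanges::reduce(reads, ignore.strand = TRUE)
  mean(GenomicRanges::countOverlaps(cpg_positions, covered,
                                    ignore.strand = TRUE) > 0L)
}
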