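`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a chromosome-size vector
#'
#' @param chrom_sizes Named numeric/integer vector of chromosome lengths in
#'   base pairs.
#' @return The same vector as a named integer vector.
#' @keywords internal
.check_chrom_sizes <- function(chrom_sizes) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes)))) {
    stop("`chrom_sizes` must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(names(chrom_sizes))) {
    stop("duplicated chromosome names in `chrom_sizes`")
  }
  if (any(is.na(chrom_sizes)) || any(chrom_sizes <= 0)) {
    stop("all chromosome lengths must be positive")
  }
  stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
}

#' Coerce read input to GRanges
#'
#' Accepts a `GRanges` of aligned reads or a path to a BED file (BED6: the
#' score column is interpreted as mapping quality when `mapq_min` is given).
#'
#' @param reads `GRanges` or BED file path.
#' @param mapq_min Optional minimum mapping quality; reads whose score falls
#'   below it are dropped. Ignored when no score is available.
#' @return `GRanges` of reads.
#' @export
as_read_granges <- function(reads, mapq_min = NULL) {
  if (is.character(reads) && length(reads) == 1L) {
    reads <- rtracklayer::import(reads, format = "BED")
  }
  if (!methods::is(reads, "GRanges")) {
    stop("`reads` must be a GRanges or a BED file path")
  }
  if (!is.null(mapq_min) && !is.null(reads$score)) {
    keep <- !is.na(reads$score) & reads$score >= mapq_min
    reads <- reads[keep]
  }
  reads
}

#' Read a chromosome-size table
#'
#' Two-column TSV (name, length), UCSC `chrom.sizes` style, no header.
#'
#' @param path File path.
#' @return Named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "integer"))
  .check_chrom_sizes(stats::setNames(tab$length, tab$chrom))
}

#' Read a plain-text gene list
#'
#' One gene identifier per line; blank lines ignored.
#'
#' @param path File path.
#' @return Character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  ids <- readLines(path)
  unique(ids[nzchar(ids)])
}

# Put two GRanges on the union of their seqlevels (for overlap queries
# between annotation layers that need not share chromosomes).
.union_seqlevels <- function(x, y) {
  lv <- union(GenomeInfoDb::seqlevels(x), GenomeInfoDb::seqlevels(y))
  GenomeInfoDb::seqlevels(x) <- lv
  GenomeInfoDb::seqlevels(y) <- lv
  list(x = x, y = y)
}

# Harmonize seqlevels of `x` to those of `ref`, failing on unknown ones.
.match_seqlevels <- function(x, ref, what = "intervals") {
  bad <- setdiff(seqlevels(x), seqlevels(ref))
  if (length(bad)) {
    stop(sprintf("%s on unknown chromosome(s): %s", what,
                 paste(bad, collapse = ", ")))
  }
  seqlevels(x) <- seqlevels(ref)
  x
}
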