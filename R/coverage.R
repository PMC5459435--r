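#' Base-resolution coverage ratio of a target
#'
#' Fraction of target bases that lie inside covered windows. Overlapping
#' target intervals are merged first, so bases shared by several targets
#' (e.g. exons of overlapping genes) are counted once.
#'
#' @param covered `covered_windows` object or a `GRanges` of covered
#'   regions.
#' @param grid Window grid (required with a `covered_windows` object).
#' @param targets `GRanges` of target intervals.
#' @param name Label for the output row.
#' @return One-row data.frame: target, covered_bases, total_bases, ratio.
#' @export
coverage_ratio <- function(covered, grid, targets, name = "target") {
  cov_gr <- .as_covered_regions(covered, grid)
  targets <- GenomicRanges::reduce(targets, ignore.strand = TRUE)
  total <- sum(as.numeric(GenomicRanges::width(targets)))
  if (total == 0) stop("empty target: coverage ratio is undefined")
  targets <- .match_seqlevels(targets, cov_gr, "targets")
  hit <- GenomicRanges::intersect(cov_gr, targets, ignore.strand = TRUE)
  cb <- sum(as.numeric(GenomicRanges::width(hit)))
  data.frame(target = name, covered_bases = cb, total_bases = total,
             ratio = cb / total)
}

#' Per-chromosome coverage ratios
#'
#' Base-resolution covered fraction of every chromosome plus a genome-wide
#' row (the length-weighted aggregate of the per-chromosome ratios).
#'
#' @inheritParams coverage_ratio
#' @param chrom_sizes Named chromosome lengths.
#' @return data.frame with one row per chromosome and a final `genome` row.
#' @export
coverage_by_chromosome <- function(covered, grid, chrom_sizes) {
  chrom_sizes <- .check_chrom_sizes(chrom_sizes)
  cov_gr <- .as_covered_regions(covered, grid)
  rows <- lapply(names(chrom_sizes), function(chr) {
    target <- GenomicRanges::GRanges(chr, IRanges::IRanges(1, chrom_sizes[[chr]]))
    GenomeInfoDb::seqlevels(target) <- GenomeInfoDb::seqlevels(cov_gr)
    coverage_ratio(cov_gr, NULL, target, name = chr)
  })
  out <- do.call(rbind, rows)
  genome <- data.frame(target = "genome",
                       covered_bases = sum(out$covered_bases),
                       total_bases = sum(out$total_bases),
                       ratio = sum(out$covered_bases) / sum(out$total_bases))
  rbind(out, genome)
}

#' Coverage increase ratio between two conditions
#'
#' Relative change of the covered fraction, (case - control) / control,
#' i.e. the control covered size is taken as 1.
#'
#' @param control,case data.frames from [coverage_by_chromosome()] (or any
#'   frames with `target` and `ratio` columns on matching targets).
#' @return data.frame: target, ratio_control, ratio_case, increase_ratio.
#' @export
coverage_increase_ratio <- function(control, case) {
  stopifnot(identical(control$target, case$target))
  data.frame(target = control$target,
             ratio_control = control$ratio,
             ratio_case = case$ratio,
             increase_ratio = (case$ratio - control$ratio) / control$ratio)
}

#' Element-level capture of named intervals
#'
#' An element (CpG island, promoter, repeat, ...) is captured iff it
#' overlaps at least one covered window by at least one base.
#'
#' @inheritParams coverage_ratio
#' @param elements `GRanges` of named elements.
#' @return List: `n_captured`, `n_total`, `fraction` (NA when no elements),
#'   and logical `captured` parallel to `elements`.
#' @export
element_capture <- function(covered, grid, elements) {
  cov_gr <- .as_covered_regions(covered, grid)
  if (length(elements) == 0L) {
    return(list(n_captured = 0L, n_total = 0L, fraction = NA_real_,
                captured = logical(0)))
  }
  elements <- .match_seqlevels(elements, cov_gr, "elements")
  hit <- GenomicRanges::countOverlaps(elements, cov_gr,
                                      ignore.strand = TRUE) > 0L
  list(n_captured = sum(hit), n_total = length(elements),
       fraction = sum(hit) / length(elements), captured = hit)
}

#' Classify windows by CpG density and summarize coverage per class
#'
#' Windows are partitioned into low (0 CpG per 100 bp), moderate (1-5) and
#' high (>= 6) density classes; the integer bounds scale with the grid
#' width for non-default widths. Per class the window count, the covered
#' fraction, and the mean 5hmC density (RPKM, i.e. counts per kb per
#' million reads) over the covered windows of the class are reported.
#'
#' @param grid Window grid.
#' @param cpg_positions `GRanges` of CpG sites.
#' @param covered `covered_windows` object.
#' @param rpkm `window_rpkm` object on the same grid.
#' @return data.frame with one row per class (low, moderate, high).
#' @export
cpg_density_strata <- function(grid, cpg_positions, covered, rpkm) {
  stopifnot(inherits(covered, "covered_windows"),
            inherits(rpkm, "window_rpkm"))
  cpg_positions <- .match_seqlevels(cpg_positions, grid, "CpG sites")
  n_cpg <- GenomicRanges::countOverlaps(grid, cpg_positions,
                                        ignore.strand = TRUE)
  scale <- GenomicRanges::width(grid) / 100
  cls <- ifelse(n_cpg < 1 * scale, "low",
                ifelse(n_cpg <= 5 * scale, "moderate", "high"))
  cls <- factor(cls, levels = c("low", "moderate", "high"))
  is_cov <- logical(length(grid))
  is_cov[covered$idx] <- TRUE
  rows <- lapply(levels(cls), function(cl) {
    in_cl <- cls == cl
    n_cov <- sum(is_cov & in_cl)
    data.frame(class = cl,
               n_windows = sum(in_cl),
               n_covered = n_cov,
               coverage_ratio = if (any(in_cl)) n_cov / sum(in_cl) else NA_real_,
               mean_rpkm = if (n_cov > 0) mean(rpkm$rpkm[is_cov & in_cl])
                           else NA_real_)
  })
  do.call(rbind, rows)
}

#' Promoter coverage and mean RPKM summary
#'
#' A promoter counts as covered iff it overlaps at least one covered
#' window; the RPKM summary is the mean, over covered promoters, of each
#' promoter's mean window RPKM.
#'
#' @param rpkm `window_rpkm` object.
#' @param covered `covered_windows` object.
#' @param promoters `GRanges` of promoters (see [build_promoters()]).
#' @param grid Window grid.
#' @return List: `n_promoters`, `n_covered`, `fraction`, `mean_rpkm` (NA
#'   when no promoter is covered).
#' @export
promoter_rpkm_summary <- function(rpkm, covered, promoters, grid) {
  stopifnot(inherits(rpkm, "window_rpkm"), inherits(covered, "covered_windows"))
  cov_gr <- covered_regions(covered, grid)
  if (length(promoters) == 0L) {
    return(list(n_promoters = 0L, n_covered = 0L, fraction = NA_real_,
                mean_rpkm = NA_real_))
  }
  promoters <- .match_seqlevels(promoters, grid, "promoters")
  hit <- GenomicRanges::countOverlaps(promoters, cov_gr,
                                      ignore.strand = TRUE) > 0L
  mean_rpkm <- NA_real_
  if (any(hit)) {
    ov <- GenomicRanges::findOverlaps(promoters[hit], grid,
                                      ignore.strand = TRUE)
    per_prom <- tapply(rpkm$rpkm[S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov), mean)
    mean_rpkm <- mean(per_prom)
  }
  list(n_promoters = length(promoters), n_covered = sum(hit),
       fraction = sum(hit) / length(promoters), mean_rpkm = mean_rpkm)
}

#' Strand-aware metagene profile around transcription start sites
#'
#' Averages window RPKM in fixed bins spanning `upstream` bp before to
#' `downstream` bp after the TSS (defaults: -2500..+500 in six 500-bp
#' bins), oriented 5' to 3' along transcription: bin 1 is the farthest
#' upstream, the last bin covers the TSS and immediate downstream. Bin
#' values are base-weighted means of overlapping window RPKM; bins clipped
#' entirely outside the chromosome are NA and excluded from set means.
#'
#' @param rpkm `window_rpkm` object.
#' @param grid Window grid.
#' @param genes Gene model data.frame with columns gene_id, chrom, strand,
#'   tss (1-based position of the first transcribed base).
#' @param gene_sets Optional named list of gene-id vectors; a profile is
#'   returned per set (plus an `all` profile).
#' @param upstream,downstream Window extent around the TSS in bp.
#' @param bin Bin width in bp; must divide upstream + downstream.
#' @return List: `per_gene` (genes x bins matrix) and `profiles`
#'   (data.frame: set, bin, mean_rpkm).
#' @export
metagene_profile <- function(rpkm, grid, genes, gene_sets = NULL,
                             upstream = 2500L, downstream = 500L,
                             bin = 500L) {
  stopifnot(inherits(rpkm, "window_rpkm"))
  span <- upstream + downstream
  if (span %% bin != 0) {
    stop("`bin` must evenly divide the profile window (upstream + downstream)")
  }
  n_bins <- span %/% bin
  chrom_len <- GenomeInfoDb::seqlengths(grid)
  n_genes <- nrow(genes)
  # bin start (1-based, genomic) for gene i, bin j, oriented by strand
  mat <- matrix(NA_real_, nrow = n_genes, ncol = n_bins,
                dimnames = list(genes$gene_id, paste0("bin", seq_len(n_bins))))
  starts <- matrix(NA_real_, n_genes, n_bins)
  for (j in seq_len(n_bins)) {
    plus <- genes$strand == "+"
    starts[plus, j] <- genes$tss[plus] - upstream + (j - 1L) * bin
    starts[!plus, j] <- genes$tss[!plus] + upstream - j * bin + 1L
  }
  gi <- rep(seq_len(n_genes), n_bins)
  bj <- rep(seq_len(n_bins), each = n_genes)
  s <- as.vector(starts)
  e <- s + bin - 1L
  len <- chrom_len[genes$chrom[gi]]
  s_cl <- pmax(s, 1)
  e_cl <- pmin(e, len)
  keep <- which(s_cl <= e_cl)
  if (length(keep)) {
    bins <- GenomicRanges::GRanges(genes$chrom[gi[keep]],
                                   IRanges::IRanges(s_cl[keep], e_cl[keep]))
    GenomeInfoDb::seqlevels(bins) <- GenomeInfoDb::seqlevels(grid)
    ov <- GenomicRanges::findOverlaps(bins, grid, ignore.strand = TRUE)
    w_ov <- GenomicRanges::width(IRanges::pintersect(
      IRanges::ranges(bins)[S4Vectors::queryHits(ov)],
      IRanges::ranges(grid)[S4Vectors::subjectHits(ov)]))
    v <- rpkm$rpkm[S4Vectors::subjectHits(ov)]
    wsum <- tapply(w_ov * v, S4Vectors::queryHits(ov), sum)
    wtot <- tapply(w_ov, S4Vectors::queryHits(ov), sum)
    idx <- as.integer(names(wsum))
    vals <- rep(NA_real_, length(keep))
    vals[idx] <- wsum / wtot
    mat[cbind(gi[keep], bj[keep])] <- vals
  }
  sets <- c(list(all = genes$gene_id), gene_sets %||% list())
  profs <- do.call(rbind, lapply(names(sets), function(nm) {
    sel <- genes$gene_id %in% sets[[nm]]
    if (!any(sel)) {
      return(data.frame(set = nm, bin = seq_len(n_bins),
                        mean_rpkm = NA_real_))
    }
    data.frame(set = nm, bin = seq_len(n_bins),
               mean_rpkm = colMeans(mat[sel, , drop = FALSE], na.rm = TRUE))
  }))
  rownames(profs) <- NULL
  list(per_gene = mat, profiles = profs)
}
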