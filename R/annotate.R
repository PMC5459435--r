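#' Build promoter intervals upstream of TSS
#'
#' The promoter of a gene is the `upstream` bp immediately 5' of its
#' transcription start site: for a plus-strand gene with (1-based) TSS t
#' the interval \[t - upstream, t - 1\], for a minus-strand gene
#' \[t + 1, t + upstream\], clipped at chromosome bounds.
#'
#' @param genes Gene model data.frame with columns gene_id, chrom, strand
#'   ("+" or "-"), tss (1-based first transcribed base).
#' @param chrom_sizes Named chromosome lengths.
#' @param upstream Promoter width in bp (default 2000).
#' @return `GRanges` with `gene_id` metadata; genes whose promoter is
#'   entirely off-chromosome are dropped.
#' @export
build_promoters <- function(genes, chrom_sizes, upstream = 2000L) {
  chrom_sizes <- .check_chrom_sizes(chrom_sizes)
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("every gene needs strand '+' or '-' to orient its promoter")
  }
  len <- chrom_sizes[genes$chrom]
  plus <- genes$strand == "+"
  s <- ifelse(plus, pmax(1, genes$tss - upstream), genes$tss + 1)
  e <- ifelse(plus, genes$tss - 1, pmin(len, genes$tss + upstream))
  keep <- s <= e
  gr <- GenomicRanges::GRanges(genes$chrom[keep],
                               IRanges::IRanges(s[keep], e[keep]),
                               strand = genes$strand[keep],
                               gene_id = genes$gene_id[keep])
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  gr
}

#' Build transcription-termination-site regions
#'
#' The TTS region extends `width` bp downstream of the transcription end:
#' \[end + 1, end + width\] for plus-strand genes, \[start - width,
#' start - 1\] for minus-strand genes, clipped at chromosome bounds.
#'
#' @param genes Gene model data.frame with columns gene_id, chrom, strand,
#'   start, end (1-based gene span).
#' @param chrom_sizes Named chromosome lengths.
#' @param width TTS region width in bp (default 1000).
#' @return `GRanges` with `gene_id` metadata.
#' @export
build_tts_regions <- function(genes, chrom_sizes, width = 1000L) {
  chrom_sizes <- .check_chrom_sizes(chrom_sizes)
  len <- chrom_sizes[genes$chrom]
  plus <- genes$strand == "+"
  s <- ifelse(plus, genes$end + 1, pmax(1, genes$start - width))
  e <- ifelse(plus, pmin(len, genes$end + width), genes$start - 1)
  keep <- s <= e
  gr <- GenomicRanges::GRanges(genes$chrom[keep],
                               IRanges::IRanges(s[keep], e[keep]),
                               strand = genes$strand[keep],
                               gene_id = genes$gene_id[keep])
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  gr
}

#' Assemble the feature index used for primary-feature assignment
#'
#' @param genes Gene model data.frame (gene_id, chrom, strand, start, end,
#'   tss).
#' @param parts `GRanges` of gene parts with `gene_id` and `part` in
#'   utr5/exon/intron/utr3.
#' @param chrom_sizes Named chromosome lengths.
#' @param promoter_upstream,tts_width Region widths in bp.
#' @return Named list of `GRanges`: promoter, utr5, exon, utr3, tts,
#'   intron (precedence order).
#' @export
build_feature_index <- function(genes, parts, chrom_sizes,
                                promoter_upstream = 2000L,
                                tts_width = 1000L) {
  list(promoter = build_promoters(genes, chrom_sizes, promoter_upstream),
       utr5 = parts[parts$part == "utr5"],
       exon = parts[parts$part == "exon"],
       utr3 = parts[parts$part == "utr3"],
       tts = build_tts_regions(genes, chrom_sizes, tts_width),
       intron = parts[parts$part == "intron"])
}

#' Assign each DhMR its primary genomic feature
#'
#' Every overlapping feature (>= 1 bp, strand ignored) is recorded; the
#' primary feature follows the precedence promoter > 5'UTR > exon > 3'UTR
#' > TTS > intron, with intergenic for regions touching no gene-linked
#' feature. Assignment is total: every record gets exactly one primary
#' feature.
#'
#' @param dhmrs DhMR data.frame from [call_dhmrs()] or a `GRanges`.
#' @param features Feature list from [build_feature_index()].
#' @return data.frame: chrom, start, end, primary_feature, gene_ids
#'   (comma-separated ids of all genes touched via any feature).
#' @export
assign_primary_feature <- function(dhmrs, features) {
  gr <- if (methods::is(dhmrs, "GRanges")) dhmrs else dhmrs_as_granges(dhmrs)
  precedence <- c("promoter", "utr5", "exon", "utr3", "tts", "intron")
  primary <- rep("intergenic", length(gr))
  genes_hit <- vector("list", length(gr))
  for (f in rev(precedence)) {
    feat <- features[[f]]
    if (is.null(feat) || length(feat) == 0L) next
    h <- .union_seqlevels(gr, feat)
    ov <- GenomicRanges::findOverlaps(h$x, h$y, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov)
    primary[q] <- f
    ids <- split(feat$gene_id[S4Vectors::subjectHits(ov)], q)
    for (nm in names(ids)) {
      i <- as.integer(nm)
      genes_hit[[i]] <- union(genes_hit[[i]], ids[[nm]])
    }
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             primary_feature = factor(primary,
                                      levels = c(precedence, "intergenic")),
             gene_ids = vapply(genes_hit, function(x) {
               paste(sort(x), collapse = ",")
             }, character(1)),
             stringsAsFactors = FALSE)
}

#' Map DhMRs to affected genes
#'
#' A gene is affected by a direction iff at least one DhMR of that
#' direction overlaps its promoter or its gene body; a gene can appear in
#' both direction sets.
#'
#' @param dhmrs DhMR data.frame (needs a `direction` column) or `GRanges`.
#' @param genes Gene model data.frame (gene_id, chrom, strand, start, end,
#'   tss).
#' @param promoters Promoter `GRanges` from [build_promoters()].
#' @return data.frame (gene_id, hyper, hypo) restricted to affected genes,
#'   with attribute `counts` = list(n_hyper, n_hypo, n_union).
#' @export
dhmrs_to_genes <- function(dhmrs, genes, promoters) {
  gr <- if (methods::is(dhmrs, "GRanges")) dhmrs else dhmrs_as_granges(dhmrs)
  bodies <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$start, genes$end),
                                   gene_id = genes$gene_id)
  extent <- c(bodies, GenomicRanges::granges(promoters))
  extent$gene_id <- c(bodies$gene_id, promoters$gene_id)
  hit_genes <- function(sub) {
    if (length(sub) == 0L) return(character(0))
    h <- .union_seqlevels(sub, extent)
    ov <- GenomicRanges::findOverlaps(h$x, h$y, ignore.strand = TRUE)
    unique(extent$gene_id[S4Vectors::subjectHits(ov)])
  }
  hyper <- hit_genes(gr[gr$direction == "hyper"])
  hypo <- hit_genes(gr[gr$direction == "hypo"])
  ids <- sort(union(hyper, hypo))
  out <- data.frame(gene_id = ids,
                    hyper = ids %in% hyper,
                    hypo = ids %in% hypo,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- list(n_hyper = length(hyper),
                              n_hypo = length(hypo),
                              n_union = length(ids))
  out
}

#' Flag imprinted genes with hydroxymethylated promoters
#'
#' Lists the imprinted genes whose promoter overlaps a hyper-DhMR (or any
#' covered region, if a coverage `GRanges` is supplied instead), carrying
#' their parent-of-origin labels.
#'
#' @param hits `GRanges` of hyper-DhMRs or covered regions, or a DhMR
#'   data.frame (its hyper records are used).
#' @param promoters Promoter `GRanges` with `gene_id`.
#' @param imprinted data.frame with columns gene_id and origin
#'   ("maternal"/"paternal"). Ids absent from the promoter catalog are
#'   skipped with a warning.
#' @return data.frame (gene_id, origin) of flagged genes.
#' @export
flag_imprinted_promoters <- function(hits, promoters, imprinted) {
  if (is.data.frame(hits)) {
    hits <- dhmrs_as_granges(hits[hits$direction == "hyper", , drop = FALSE])
  }
  stopifnot(is.data.frame(imprinted),
            all(c("gene_id", "origin") %in% names(imprinted)))
  unknown <- setdiff(imprinted$gene_id, promoters$gene_id)
  if (length(unknown)) {
    warning(sprintf("%d imprinted gene id(s) not in the promoter catalog; skipped",
                    length(unknown)))
  }
  imp <- imprinted[imprinted$gene_id %in% promoters$gene_id, , drop = FALSE]
  if (nrow(imp) == 0L || length(hits) == 0L) {
    return(imp[0, c("gene_id", "origin"), drop = FALSE])
  }
  prom <- promoters[promoters$gene_id %in% imp$gene_id]
  h <- .union_seqlevels(prom, hits)
  ov <- GenomicRanges::countOverlaps(h$x, h$y, ignore.strand = TRUE) > 0L
  flagged <- unique(prom$gene_id[ov])
  out <- imp[imp$gene_id %in% flagged, c("gene_id", "origin"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Attribute DhMRs to repeat classes
#'
#' Many-to-many attribution: a DhMR touching several repeat classes counts
#' toward each. Reports per class the number of DhMRs touching it, the
#' total repeat bases, and the DhMR density per megabase of repeat.
#'
#' @param dhmrs DhMR data.frame or `GRanges`.
#' @param repeats `GRanges` of repeats with a `class` column (LINE, SINE,
#'   LTR, DNA, ...).
#' @return data.frame: class, n_dhmrs, class_bases, dhmrs_per_mb.
#' @export
dhmr_repeat_classes <- function(dhmrs, repeats) {
  gr <- if (methods::is(dhmrs, "GRanges")) dhmrs else dhmrs_as_granges(dhmrs)
  classes <- sort(unique(repeats$class))
  rows <- lapply(classes, function(cl) {
    sub <- repeats[repeats$class == cl]
    bases <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(sub))))
    n <- if (length(gr)) {
      h <- .union_seqlevels(gr, sub)
      sum(GenomicRanges::countOverlaps(h$x, h$y, ignore.strand = TRUE) > 0L)
    } else 0L
    data.frame(class = cl, n_dhmrs = n, class_bases = bases,
               dhmrs_per_mb = n / (bases / 1e6))
  })
  do.call(rbind, rows)
}
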