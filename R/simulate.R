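#' Simulation configuration for the toy hMeDIP-seq study
#'
#' Defines the conditions of the simulated two-library design: a small
#' multi-chromosome genome, gene models with 5'UTR/exon/intron/3'UTR
#' parts, a CpG landscape with island clusters over a low background,
#' labeled repeat classes, and planted hyper-/hypo-hydroxymethylated
#' 100-bp windows under a negative-binomial count model. The default
#' library-size ratio matches the two pooled sperm libraries the package
#' targets (44,263,854 exposed / 35,995,280 control reads of 51 bp,
#' at desk scale).
#'
#' @param seed Integer seed; every generator stage derives its own stream
#'   from it, so identical configs give identical outputs.
#' @param chrom_sizes Named chromosome lengths (default 2 x 500 kb, i.e.
#'   10,000 windows of 100 bp).
#' @param n_genes Number of gene models to place.
#' @param gene_part_lengths Named bp lengths for parts utr5, exon, intron,
#'   utr3; each gene is laid out utr5-exon-intron-exon-utr3.
#' @param n_cgis Number of CpG islands (800 bp each, grid-aligned).
#' @param cgi_cpg_per_100bp CpG count per 100 bp inside islands.
#' @param background_cpg_per_100bp Mean background CpG count per 100 bp.
#' @param repeat_fraction Named genome fractions per repeat class.
#' @param read_length Read length in bp (default 51).
#' @param depth_per_window Expected reads per 100-bp window per library.
#' @param dispersion NB dispersion phi of window counts (variance =
#'   mu + phi mu^2); 0 gives Poisson counts.
#' @param n_hyper,n_hypo Number of planted hyper-/hypo-windows.
#' @param fold_change Planted fold change (> 1).
#' @param library_size_ratio Exposed/control expected total-read ratio.
#' @param window_width Grid width in bp (default 100).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_sizes = c(chr1 = 500000L, chr2 = 500000L),
                              n_genes = 60L,
                              gene_part_lengths = c(utr5 = 200L, exon = 300L,
                                                    intron = 800L, utr3 = 300L),
                              n_cgis = 40L,
                              cgi_cpg_per_100bp = 10L,
                              background_cpg_per_100bp = 1,
                              repeat_fraction = c(LINE = 0.10, SINE = 0.08,
                                                  LTR = 0.04, DNA = 0.03),
                              read_length = 51L,
                              depth_per_window = 10,
                              dispersion = 0.05,
                              n_hyper = 50L,
                              n_hypo = 10L,
                              fold_change = 4,
                              library_size_ratio = 44263854 / 35995280,
                              window_width = 100L) {
  cfg <- list(seed = as.integer(seed), chrom_sizes = .check_chrom_sizes(chrom_sizes),
              n_genes = as.integer(n_genes),
              gene_part_lengths = gene_part_lengths,
              n_cgis = as.integer(n_cgis),
              cgi_cpg_per_100bp = cgi_cpg_per_100bp,
              background_cpg_per_100bp = background_cpg_per_100bp,
              repeat_fraction = repeat_fraction,
              read_length = as.integer(read_length),
              depth_per_window = depth_per_window,
              dispersion = dispersion,
              n_hyper = as.integer(n_hyper), n_hypo = as.integer(n_hypo),
              fold_change = fold_change,
              library_size_ratio = library_size_ratio,
              window_width = as.integer(window_width))
  if (cfg$n_genes < 0 || cfg$n_cgis < 0 || cfg$n_hyper < 0 || cfg$n_hypo < 0) {
    stop("counts must be non-negative")
  }
  if (!all(c("utr5", "exon", "intron", "utr3") %in% names(cfg$gene_part_lengths))) {
    stop("`gene_part_lengths` needs utr5, exon, intron and utr3 entries")
  }
  if (any(cfg$gene_part_lengths <= 0)) stop("gene part lengths must be positive")
  if (cfg$fold_change <= 1) stop("`fold_change` must exceed 1")
  if (cfg$cgi_cpg_per_100bp < 0 || cfg$background_cpg_per_100bp < 0) {
    stop("CpG densities must be >= 0")
  }
  if (any(cfg$repeat_fraction < 0) || sum(cfg$repeat_fraction) >= 1) {
    stop("repeat fractions must be >= 0 and sum to < 1")
  }
  if (cfg$read_length <= 0) stop("`read_length` must be positive")
  if (cfg$depth_per_window < 0) stop("`depth_per_window` must be >= 0")
  if (cfg$dispersion < 0) stop("`dispersion` must be >= 0")
  if (cfg$library_size_ratio <= 0) stop("`library_size_ratio` must be positive")
  n_windows <- sum(ceiling(cfg$chrom_sizes / cfg$window_width))
  if (cfg$n_hyper + cfg$n_hypo > n_windows) {
    stop(sprintf("cannot plant %d signals in %d windows",
                 cfg$n_hyper + cfg$n_hypo, n_windows))
  }
  structure(cfg, class = "simulation_config")
}

# Gene layout in transcriptional order; exon appears twice around the intron.
.gene_part_order <- c("utr5", "exon", "intron", "exon", "utr3")

.gene_total_length <- function(part_lengths) {
  sum(part_lengths[.gene_part_order])
}

#' Build a deterministic toy genome
#'
#' Places non-overlapping gene models (with room for a 2-kb promoter and a
#' 1-kb TTS region), grid-aligned CpG islands, a Poisson CpG background
#' with the configured island density, disjoint labeled repeats, and gene
#' sets with controlled overlaps (bivalent genes are exactly the
#' intersection of the H3K4me3 and H3K27me3 sets). Deterministic for a
#' fixed config.
#'
#' @param config `simulation_config`.
#' @return A `toy_genome` list: chrom_sizes, window_width, genes (df:
#'   gene_id, chrom, strand, start, end, tss; 1-based closed), parts
#'   (`GRanges` with gene_id, part), cgis, repeats (`GRanges` with class),
#'   cpg (width-1 `GRanges`), gene_sets (named list), imprinted (df:
#'   gene_id, origin).
#' @export
build_toy_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  cs <- config$chrom_sizes
  pl <- config$gene_part_lengths
  gene_len <- .gene_total_length(pl)
  slot_len <- gene_len + 2000L + 1000L + 500L
  slots_per_chrom <- floor(cs / slot_len)
  if (sum(slots_per_chrom) < config$n_genes) {
    stop(sprintf(
      "gene models of %d bp (plus flanks) do not fit: %d genes requested, %d slots available",
      gene_len, config$n_genes, sum(slots_per_chrom)))
  }
  # allocate genes to chromosomes proportionally to available slots
  alloc <- floor(config$n_genes * slots_per_chrom / sum(slots_per_chrom))
  while (sum(alloc) < config$n_genes) {
    i <- which.max(slots_per_chrom - alloc)
    alloc[i] <- alloc[i] + 1L
  }
  genes <- list(); parts <- list()
  gid <- 0L
  for (chr in names(cs)) {
    n_c <- alloc[[chr]]
    if (n_c == 0L) next
    chosen <- sort(sample.int(slots_per_chrom[[chr]], n_c))
    for (slot in chosen) {
      gid <- gid + 1L
      id <- sprintf("G%03d", gid)
      offset <- sample.int(400L, 1L) - 1L
      s <- (slot - 1L) * slot_len + 2000L + 1L + offset
      e <- s + gene_len - 1L
      strand <- sample(c("+", "-"), 1L)
      tss <- if (strand == "+") s else e
      genes[[gid]] <- data.frame(gene_id = id, chrom = chr, strand = strand,
                                 start = s, end = e, tss = tss,
                                 stringsAsFactors = FALSE)
      lens <- unname(pl[.gene_part_order])
      if (strand == "+") {
        p_start <- s + cumsum(c(0L, lens[-length(lens)]))
      } else {
        p_end <- e - cumsum(c(0L, lens[-length(lens)]))
        p_start <- p_end - lens + 1L
      }
      parts[[gid]] <- data.frame(chrom = chr, start = p_start,
                                 end = p_start + lens - 1L,
                                 strand = strand,
                                 gene_id = id, part = .gene_part_order,
                                 stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, genes)
  parts_df <- do.call(rbind, parts)
  parts_gr <- GenomicRanges::GRanges(parts_df$chrom,
                                     IRanges::IRanges(parts_df$start,
                                                      parts_df$end),
                                     strand = parts_df$strand,
                                     gene_id = parts_df$gene_id,
                                     part = parts_df$part)
  GenomeInfoDb::seqlevels(parts_gr) <- names(cs)

  # CpG islands: 8 consecutive grid windows (800 bp), disjoint
  w <- config$window_width
  cgi_windows <- 8L
  cgi_alloc <- floor(config$n_cgis * cs / sum(cs))
  while (sum(cgi_alloc) < config$n_cgis) {
    i <- which.max(cs - cgi_alloc)
    cgi_alloc[i] <- cgi_alloc[i] + 1L
  }
  cgis <- list()
  for (chr in names(cs)) {
    n_c <- cgi_alloc[[chr]]
    if (n_c == 0L) next
    n_blocks <- floor(cs[[chr]] / (w * cgi_windows))
    if (n_blocks < n_c) {
      stop(sprintf("cannot place %d CpG islands on %s", n_c, chr))
    }
    blocks <- sort(sample.int(n_blocks, n_c))
    s <- (blocks - 1L) * w * cgi_windows + 1L
    cgis[[chr]] <- data.frame(chrom = chr, start = s,
                              end = s + w * cgi_windows - 1L)
  }
  cgis <- do.call(rbind, cgis)
  cgi_gr <- GenomicRanges::GRanges(cgis$chrom,
                                   IRanges::IRanges(cgis$start, cgis$end),
                                   name = sprintf("CGI%03d", seq_len(nrow(cgis))))
  GenomeInfoDb::seqlevels(cgi_gr) <- names(cs)

  # CpG sites: Poisson background per window, fixed island density
  grid <- make_windows(cs, w)
  in_cgi <- GenomicRanges::countOverlaps(grid, cgi_gr,
                                         ignore.strand = TRUE) > 0L
  dens_scale <- GenomicRanges::width(grid) / 100
  n_cpg <- stats::rpois(length(grid),
                        config$background_cpg_per_100bp * dens_scale)
  n_cpg[in_cgi] <- round(config$cgi_cpg_per_100bp * dens_scale[in_cgi])
  n_cpg <- pmin(n_cpg, GenomicRanges::width(grid) - 1L)
  nz <- which(n_cpg > 0L)
  pos <- lapply(nz, function(i) {
    s <- GenomicRanges::start(grid)[i]
    wd <- GenomicRanges::width(grid)[i]
    s + sort(sample.int(wd - 1L, n_cpg[i])) - 1L
  })
  cpg_gr <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(grid))[nz], n_cpg[nz]),
    IRanges::IRanges(unlist(pos), width = 1L))
  GenomeInfoDb::seqlevels(cpg_gr) <- names(cs)

  # repeats: disjoint by construction (one repeat per sampled 1-kb block)
  repeats <- list()
  block <- 1000L
  for (chr in names(cs)) {
    n_blocks <- floor(cs[[chr]] / block)
    avail <- seq_len(n_blocks)
    for (cl in names(config$repeat_fraction)) {
      target <- config$repeat_fraction[[cl]] * cs[[chr]]
      need <- ceiling(target / 500)  # mean repeat length ~500 bp
      need <- min(need, length(avail))
      if (need == 0L) next
      pick <- sample(avail, need)
      avail <- setdiff(avail, pick)
      len <- sample(200:800, need, replace = TRUE)
      s <- (pick - 1L) * block + sample.int(block - 800L, need, replace = TRUE)
      repeats[[paste(chr, cl)]] <- data.frame(chrom = chr, start = s,
                                              end = s + len - 1L, class = cl)
    }
  }
  repeats <- do.call(rbind, repeats)
  rep_gr <- GenomicRanges::GRanges(repeats$chrom,
                                   IRanges::IRanges(repeats$start,
                                                    repeats$end),
                                   class = repeats$class)
  GenomeInfoDb::seqlevels(rep_gr) <- names(cs)
  rep_gr <- GenomicRanges::sort(rep_gr)

  # gene sets with controlled overlaps
  ids <- genes$gene_id
  n <- length(ids)
  expressed <- sort(sample(ids, round(0.40 * n)))
  highly_expressed <- sort(sample(expressed,
                                  min(length(expressed), round(0.10 * n))))
  repressed <- sort(sample(setdiff(ids, expressed), round(0.15 * n)))
  h3k4me3 <- sort(sample(ids, round(0.30 * n)))
  bivalent <- sort(sample(h3k4me3, max(1L, round(0.10 * n))))
  h3k27me3 <- sort(c(bivalent,
                     sample(setdiff(ids, h3k4me3), round(0.08 * n))))
  h3k4me2 <- sort(unique(c(sample(h3k4me3, round(0.8 * length(h3k4me3))),
                           sample(ids, round(0.15 * n)))))
  imp_ids <- sample(ids, min(n, 6L))
  imprinted <- data.frame(gene_id = imp_ids,
                          origin = rep(c("maternal", "paternal"),
                                       length.out = length(imp_ids)),
                          stringsAsFactors = FALSE)
  genome <- list(chrom_sizes = cs, window_width = w,
                 genes = genes, parts = parts_gr, cgis = cgi_gr,
                 repeats = rep_gr, cpg = cpg_gr,
                 gene_sets = list(expressed = expressed,
                                  highly_expressed = highly_expressed,
                                  repressed = repressed,
                                  h3k4me2 = h3k4me2,
                                  h3k4me3 = h3k4me3,
                                  h3k27me3 = h3k27me3,
                                  bivalent = bivalent),
                 imprinted = imprinted)
  class(genome) <- "toy_genome"
  genome
}

#' @export
print.toy_genome <- function(x, ...) {
  cat(sprintf(
    "<toy_genome> %d chromosome(s), %s bp; %d genes, %d CGIs, %d repeats, %d CpGs\n",
    length(x$chrom_sizes), format(sum(x$chrom_sizes), big.mark = ","),
    nrow(x$genes), length(x$cgis), length(x$repeats), length(x$cpg)))
  invisible(x)
}

#' Plant differential hydroxymethylation signals
#'
#' Samples `n_hyper + n_hypo` disjoint grid windows and assigns them
#' directions and the configured fold change. Hyper windows have higher
#' expected counts in the exposed library, hypo windows in the control.
#'
#' @param genome `toy_genome`.
#' @param config `simulation_config`.
#' @return `GRanges` of planted windows with `direction` and `fold`
#'   metadata (a `planted_signal`).
#' @export
plant_dhmr_signals <- function(genome, config) {
  stopifnot(inherits(genome, "toy_genome"),
            inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  grid <- make_windows(genome$chrom_sizes, config$window_width)
  n_signal <- config$n_hyper + config$n_hypo
  if (n_signal > length(grid)) {
    stop(sprintf("requested %d planted windows but only %d are available",
                 n_signal, length(grid)))
  }
  idx <- sample.int(length(grid), n_signal)
  sig <- grid[idx]
  sig$direction <- rep(c("hyper", "hypo"),
                       c(config$n_hyper, config$n_hypo))
  sig$fold <- rep(config$fold_change, n_signal)
  GenomicRanges::sort(sig)
}

#' Simulate an hMeDIP-seq read library
#'
#' Draws a count per 100-bp window from NB(mean, phi) (Poisson when phi =
#' 0) and places that many reads uniformly within the window, so reads may
#' overhang window edges. The expected window mean is `depth_per_window`,
#' multiplied by `fold_change` in planted windows of the matching
#' direction (hypo windows are elevated in the control, hyper in the
#' exposed library) and by `library_size_ratio` throughout the exposed
#' library. Read starts are clamped so every read lies inside its
#' chromosome.
#'
#' @param genome `toy_genome`.
#' @param signal Planted-signal `GRanges` from [plant_dhmr_signals()].
#' @param config `simulation_config`.
#' @param condition `"control"` or `"exposed"`.
#' @return `GRanges` of reads (BED6-style: name, score 0, random strand).
#' @export
simulate_reads <- function(genome, signal, config,
                           condition = c("control", "exposed")) {
  stopifnot(inherits(genome, "toy_genome"),
            inherits(config, "simulation_config"))
  condition <- match.arg(condition)
  set.seed(config$seed + if (condition == "control") 2L else 3L)
  if (config$depth_per_window < 0) stop("`depth_per_window` must be >= 0")
  grid <- make_windows(genome$chrom_sizes, config$window_width)
  mult <- rep(1, length(grid))
  if (length(signal) > 0L) {
    hits <- GenomicRanges::findOverlaps(signal, grid, type = "equal")
    dirs <- signal$direction[S4Vectors::queryHits(hits)]
    folds <- signal$fold[S4Vectors::queryHits(hits)]
    widx <- S4Vectors::subjectHits(hits)
    boost <- if (condition == "control") dirs == "hypo" else dirs == "hyper"
    mult[widx[boost]] <- folds[boost]
  }
  mu <- config$depth_per_window * mult *
    (GenomicRanges::width(grid) / config$window_width)
  if (condition == "exposed") mu <- mu * config$library_size_ratio
  counts <- if (config$dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$dispersion)
  }
  total <- sum(counts)
  if (total == 0L) {
    gr <- GenomicRanges::GRanges()
    GenomeInfoDb::seqlevels(gr) <- names(genome$chrom_sizes)
    return(gr)
  }
  ws <- rep(GenomicRanges::start(grid), counts)
  wd <- rep(GenomicRanges::width(grid), counts)
  chr <- rep(as.character(GenomicRanges::seqnames(grid)), counts)
  chrom_len <- genome$chrom_sizes[chr]
  starts <- ws + floor(stats::runif(total) * wd)
  starts <- pmin(starts, chrom_len - config$read_length + 1L)
  starts <- pmax(starts, 1L)
  reads <- GenomicRanges::GRanges(chr,
                                  IRanges::IRanges(starts,
                                                   width = config$read_length),
                                  strand = sample(c("+", "-"), total,
                                                  replace = TRUE),
                                  name = sprintf("%s_read_%07d", condition,
                                                 seq_len(total)),
                                  score = 0L)
  GenomeInfoDb::seqlevels(reads) <- names(genome$chrom_sizes)
  GenomicRanges::sort(reads, ignore.strand = TRUE)
}
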