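# Shared helpers: small simulation configs, hand-built track objects and
# brute-force oracles kept independent of the package's interval code.

tiny_config <- function(...) {
  defaults <- list(seed = 11L,
                   chrom_sizes = c(chrA = 100000L, chrB = 80000L),
                   n_genes = 12L, n_cgis = 6L,
                   n_hyper = 5L, n_hypo = 2L,
                   depth_per_window = 2)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

make_counts <- function(counts, library_total = sum(counts)) {
  structure(list(counts = as.integer(counts),
                 library_total = as.integer(library_total)),
            class = "window_counts")
}

make_rpkm <- function(rpkm, library_total = 1e6) {
  structure(list(rpkm = as.numeric(rpkm), library_total = library_total),
            class = "window_rpkm")
}

gr <- function(chrom, start, end = NULL, width = NULL, ...) {
  r <- if (!is.null(width)) IRanges::IRanges(start, width = width)
       else IRanges::IRanges(start, end)
  GenomicRanges::GRanges(chrom, r, ...)
}

# O(n*m) overlap-count oracle on plain data.frames (1-based closed coords)
brute_window_counts <- function(win, reads) {
  vapply(seq_len(nrow(win)), function(i) {
    sum(reads$chrom == win$chrom[i] &
          reads$start <= win$end[i] & reads$end >= win$start[i])
  }, numeric(1))
}

# base-resolution coverage-ratio oracle: walks every target base
brute_covered_fraction <- function(cov, target) {
  total <- 0L; hit <- 0L
  for (i in seq_len(nrow(target))) {
    for (b in target$start[i]:target$end[i]) {
      total <- total + 1L
      inside <- any(cov$chrom == target$chrom[i] &
                      cov$start <= b & cov$end >= b)
      if (inside) hit <- hit + 1L
    }
  }
  hit / total
}

# precedence oracle for primary-feature assignment
brute_primary_feature <- function(region, feats) {
  for (f in c("promoter", "utr5", "exon", "utr3", "tts", "intron")) {
    df <- feats[[f]]
    if (is.null(df) || nrow(df) == 0L) next
    ov <- any(df$chrom == region$chrom & df$start <= region$end &
                df$end >= region$start)
    if (ov) return(f)
  }
  "intergenic"
}

# exhaustive two-sided binomial tail oracle (minimum-likelihood method)
enum_binom_two_sided <- function(a, t) {
  probs <- choose(t, 0:t) / 2^t
  sum(probs[probs <= probs[a + 1] * (1 + 1e-7)])
}
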