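test_that("configuration invariants are enforced", {
  expect_error(simulation_config(fold_change = 1), "exceed 1")
  expect_error(simulation_config(dispersion = -0.1), ">= 0")
  expect_error(simulation_config(repeat_fraction = c(LINE = 0.9, SINE = 0.2)),
               "sum")
  expect_error(simulation_config(chrom_sizes = c(chr1 = 10000L),
                                 n_hyper = 200L),
               "plant")
  expect_error(tiny_config(n_genes = 5000L) |> build_toy_genome(), "fit")
})

test_that("toy genomes are deterministic and respect their invariants", {
  cfg <- tiny_config()
  g1 <- build_toy_genome(cfg)
  g2 <- build_toy_genome(cfg)
  expect_identical(g1$genes, g2$genes)
  expect_identical(GenomicRanges::start(g1$cpg), GenomicRanges::start(g2$cpg))
  expect_identical(g1$gene_sets, g2$gene_sets)

  expect_equal(nrow(g1$genes), cfg$n_genes)
  len <- cfg$chrom_sizes[g1$genes$chrom]
  expect_true(all(g1$genes$start >= 1 & g1$genes$end <= len))

  # parts of each gene are disjoint and contiguous in transcriptional order
  for (id in g1$genes$gene_id) {
    p <- g1$parts[g1$parts$gene_id == id]
    p <- p[order(GenomicRanges::start(p))]
    expect_true(all(GenomicRanges::start(p)[-1] ==
                      GenomicRanges::end(p)[-length(p)] + 1))
  }

  # CpG positions strictly increasing per chromosome
  for (chr in names(cfg$chrom_sizes)) {
    pos <- GenomicRanges::start(g1$cpg[GenomicRanges::seqnames(g1$cpg) == chr])
    expect_true(all(diff(pos) > 0))
  }

  # bivalent set is exactly the H3K4me3/H3K27me3 intersection
  expect_setequal(g1$gene_sets$bivalent,
                  intersect(g1$gene_sets$h3k4me3, g1$gene_sets$h3k27me3))
})

test_that("CpG islands produce high-density windows for the stratifier", {
  cfg <- tiny_config(n_cgis = 10L, cgi_cpg_per_100bp = 10L)
  g <- build_toy_genome(cfg)
  grid <- make_windows(cfg$chrom_sizes, cfg$window_width)
  dummy_cov <- covered_windows(make_counts(rep(1L, length(grid))))
  dummy_rpkm <- make_rpkm(rep(1, length(grid)))
  strata <- cpg_density_strata(grid, g$cpg, dummy_cov, dummy_rpkm)
  expect_gte(strata$n_windows[strata$class == "high"], 10L)
})

test_that("planted signals are disjoint, grid-aligned and direction-complete", {
  cfg <- tiny_config(n_hyper = 0L, n_hypo = 0L)
  g <- build_toy_genome(cfg)
  expect_length(plant_dhmr_signals(g, cfg), 0L)

  cfg2 <- tiny_config(n_hyper = 50L, n_hypo = 7L)
  g2 <- build_toy_genome(cfg2)
  sig <- plant_dhmr_signals(g2, cfg2)
  expect_length(sig, 57L)
  expect_equal(sum(sig$direction == "hyper"), 50L)
  expect_true(all(GenomicRanges::start(sig) %% 100 == 1))
  expect_equal(length(GenomicRanges::reduce(sig)), 57L)  # pairwise disjoint
})

test_that("read simulation honours length, depth and the Poisson count model", {
  cfg <- tiny_config(depth_per_window = 0)
  g <- build_toy_genome(cfg)
  sig <- plant_dhmr_signals(g, cfg)
  expect_length(simulate_reads(g, sig, cfg, "control"), 0L)

  cfg2 <- simulation_config(seed = 71, chrom_sizes = c(chrA = 1000000L),
                            n_genes = 30L, n_hyper = 0L, n_hypo = 0L,
                            depth_per_window = 2, dispersion = 0)
  g2 <- build_toy_genome(cfg2)
  sig2 <- plant_dhmr_signals(g2, cfg2)
  reads <- simulate_reads(g2, sig2, cfg2, "control")
  expect_true(all(GenomicRanges::width(reads) == 51))
  expect_true(all(GenomicRanges::end(reads) <= 1000000L))

  # drawn count per window = reads starting in it; mean within 3 SE of 2
  grid <- make_windows(cfg2$chrom_sizes, 100)
  starts <- GenomicRanges::resize(reads, 1, fix = "start", ignore.strand = TRUE)
  drawn <- GenomicRanges::countOverlaps(grid, starts, ignore.strand = TRUE)
  interior <- drawn[-length(drawn)]
  se <- sqrt(2 / length(interior))
  expect_lt(abs(mean(interior) - 2), 3 * se)
  # Poisson: variance ~ mean
  expect_lt(abs(var(interior) / mean(interior) - 1), 0.1)
})

test_that("overdispersed counts show the mu + phi mu^2 variance law", {
  cfg <- simulation_config(seed = 72, chrom_sizes = c(chrA = 1000000L),
                           n_genes = 30L, n_hyper = 0L, n_hypo = 0L,
                           depth_per_window = 10, dispersion = 0.2)
  g <- build_toy_genome(cfg)
  sig <- plant_dhmr_signals(g, cfg)
  reads <- simulate_reads(g, sig, cfg, "control")
  grid <- make_windows(cfg$chrom_sizes, 100)
  starts <- GenomicRanges::resize(reads, 1, fix = "start", ignore.strand = TRUE)
  drawn <- GenomicRanges::countOverlaps(grid, starts, ignore.strand = TRUE)
  drawn <- drawn[-length(drawn)]
  mu <- mean(drawn)
  expect_lt(abs(var(drawn) - (mu + 0.2 * mu^2)), 2.5)
})

test_that("planted windows converge to the configured fold change", {
  cfg <- simulation_config(seed = 73, chrom_sizes = c(chrA = 1000000L),
                           n_genes = 30L, n_hyper = 300L, n_hypo = 0L,
                           depth_per_window = 20, dispersion = 0,
                           fold_change = 4, library_size_ratio = 1)
  g <- build_toy_genome(cfg)
  sig <- plant_dhmr_signals(g, cfg)
  grid <- make_windows(cfg$chrom_sizes, 100)
  planted <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(sig, grid, type = "equal"))
  drawn_mean <- function(condition) {
    reads <- simulate_reads(g, sig, cfg, condition)
    starts <- GenomicRanges::resize(reads, 1, fix = "start",
                                    ignore.strand = TRUE)
    mean(GenomicRanges::countOverlaps(grid, starts,
                                      ignore.strand = TRUE)[planted])
  }
  ratio <- drawn_mean("exposed") / drawn_mean("control")
  expect_lt(abs(ratio - 4), 0.2)
})

test_that("the exposed library is scaled by the library-size ratio", {
  cfg <- tiny_config(depth_per_window = 5, n_hyper = 0L, n_hypo = 0L,
                     dispersion = 0)
  g <- build_toy_genome(cfg)
  sig <- plant_dhmr_signals(g, cfg)
  n_c <- length(simulate_reads(g, sig, cfg, "control"))
  n_e <- length(simulate_reads(g, sig, cfg, "exposed"))
  expect_lt(abs(n_e / n_c - cfg$library_size_ratio), 0.05)
})

test_that("fixture bundles round-trip and are byte-identical across runs", {
  cfg <- tiny_config(seed = 3L)
  g <- build_toy_genome(cfg)
  s <- plant_dhmr_signals(g, cfg)
  rc <- simulate_reads(g, s, cfg, "control")
  re <- simulate_reads(g, s, cfg, "exposed")
  d1 <- withr::local_tempdir()
  write_fixtures(g, s, rc, re, d1)
  b <- read_fixture_bundle(d1)

  expect_identical(b$chrom_sizes, g$chrom_sizes)
  expect_equal(b$genes[order(b$genes$gene_id), ],
               g$genes[order(g$genes$gene_id), ],
               ignore_attr = TRUE)
  expect_identical(GenomicRanges::start(b$cpg), GenomicRanges::start(g$cpg))
  expect_identical(GenomicRanges::start(b$truth), GenomicRanges::start(s))
  expect_identical(b$truth$direction, s$direction)
  expect_identical(GenomicRanges::start(b$reads_control),
                   GenomicRanges::start(rc))
  expect_identical(as.character(b$repeats$class), as.character(g$repeats$class))
  nm <- sort(names(g$gene_sets))
  expect_identical(lapply(b$gene_sets[nm], sort), lapply(g$gene_sets[nm], sort))
  expect_equal(sum(vapply(b$gene_sets, length, 0L)) >= 0, TRUE)
  expect_identical(b$imprinted$gene_id, g$imprinted$gene_id)

  # truth table rows = n_hyper + n_hypo
  tt <- read.table(file.path(d1, "truth.tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tt), cfg$n_hyper + cfg$n_hypo)

  # determinism: a second bundle from the same config is byte-identical
  d2 <- withr::local_tempdir()
  g2 <- build_toy_genome(cfg)
  s2 <- plant_dhmr_signals(g2, cfg)
  write_fixtures(g2, s2, simulate_reads(g2, s2, cfg, "control"),
                 simulate_reads(g2, s2, cfg, "exposed"), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("GFF (1-based closed) and BED (0-based half-open) agree on one gene", {
  cfg <- tiny_config(seed = 5L)
  g <- build_toy_genome(cfg)
  s <- plant_dhmr_signals(g, cfg)
  d <- withr::local_tempdir()
  write_fixtures(g, s, simulate_reads(g, s, cfg, "control"),
                 simulate_reads(g, s, cfg, "exposed"), d)

  gene <- g$genes[1, ]
  gff_lines <- readLines(file.path(d, "genes.gff3"))
  gene_line <- grep(sprintf("ID=%s($|;)", gene$gene_id), gff_lines,
                    value = TRUE)[1]
  f <- strsplit(gene_line, "\t")[[1]]
  expect_equal(as.integer(f[4]), gene$start)      # GFF start: 1-based
  expect_equal(as.integer(f[5]), gene$end)        # GFF end: closed

  cgi <- g$cgis[1]
  bed_line <- readLines(file.path(d, "cgis.bed"))[1]
  b <- strsplit(bed_line, "\t")[[1]]
  expect_equal(as.integer(b[2]), GenomicRanges::start(cgi) - 1L)  # 0-based
  expect_equal(as.integer(b[3]), GenomicRanges::end(cgi))         # half-open
})
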