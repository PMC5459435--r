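test_that("coverage ratio is the base fraction of the target inside covered windows", {
  grid <- make_windows(c(c1 = 1000), 100)
  cov <- covered_windows(make_counts(c(0, 1, rep(0, 8))))  # window [101,200]

  inside <- coverage_ratio(cov, grid, gr("c1", 110, 190))
  expect_equal(inside$ratio, 1)
  disjoint <- coverage_ratio(cov, grid, gr("c1", 301, 400))
  expect_equal(disjoint$ratio, 0)

  # BED-style target [50,250) with only [100,200) covered: 100/200
  half <- coverage_ratio(cov, grid, gr("c1", 51, 250))
  expect_equal(half$ratio, 0.5)
  expect_equal(half$covered_bases, 100)

  expect_error(coverage_ratio(cov, grid, GenomicRanges::GRanges()), "empty")
})

test_that("coverage ratio matches a base-resolution brute-force oracle", {
  set.seed(33)
  for (i in 1:40) {
    grid <- make_windows(c(c1 = 500), 50)
    counts <- rbinom(10, 1, 0.4)
    if (sum(counts) == 0) counts[1] <- 1L
    cov <- covered_windows(make_counts(counts))
    s <- sample(450, 3)
    targets <- gr("c1", s, pmin(s + sample(20:120, 3, replace = TRUE), 500))
    got <- coverage_ratio(cov, grid, targets)$ratio
    cov_df <- data.frame(chrom = "c1",
                         start = GenomicRanges::start(grid)[cov$idx],
                         end = GenomicRanges::end(grid)[cov$idx])
    red <- GenomicRanges::reduce(targets)
    tgt_df <- data.frame(chrom = "c1", start = GenomicRanges::start(red),
                         end = GenomicRanges::end(red))
    expect_equal(got, brute_covered_fraction(cov_df, tgt_df))
  }
})

test_that("per-chromosome ratios aggregate to the genome-wide ratio", {
  cs <- c(c1 = 1000, c2 = 500)
  grid <- make_windows(cs, 100)
  set.seed(2)
  cov <- covered_windows(make_counts(rbinom(15, 1, 0.5)))
  tab <- coverage_by_chromosome(cov, grid, cs)
  per_chrom <- tab[tab$target != "genome", ]
  genome <- tab[tab$target == "genome", ]
  expect_equal(sum(per_chrom$ratio * per_chrom$total_bases) /
                 sum(per_chrom$total_bases), genome$ratio)
})

test_that("element capture uses the any-part rule and is monotone", {
  grid <- make_windows(c(c1 = 1000), 100)
  cov <- covered_windows(make_counts(c(1, 0, 1, 0, 1, 0, 0, 0, 0, 0)))
  elements <- gr("c1", c(95, 295, 401, 880), c(160, 390, 480, 920),
                 name = paste0("e", 1:4))
  cap <- element_capture(cov, grid, elements)
  expect_equal(cap$n_captured, 3L)
  expect_equal(cap$fraction, 0.75)

  none <- element_capture(covered_windows(make_counts(rep(0, 10))), grid,
                          elements)
  expect_equal(none$n_captured, 0L)

  # adding covered windows never loses captured elements
  more <- covered_windows(make_counts(c(1, 0, 1, 0, 1, 0, 0, 0, 1, 0)))
  expect_gte(element_capture(more, grid, elements)$n_captured,
             cap$n_captured)

  empty <- element_capture(cov, grid, GenomicRanges::GRanges())
  expect_true(is.na(empty$fraction))
})

test_that("CpG density classes partition windows at the 0 / 1-5 / >=6 bounds", {
  grid <- make_windows(c(c1 = 400), 100)
  # window1: 0 CpG, window2: 5, window3: 6, window4: 1
  cpg <- gr("c1", c(101 + seq(0, 80, by = 20), 201 + seq(0, 99, by = 18),
                    310), width = 1)
  cov <- covered_windows(make_counts(c(1, 1, 0, 0)))
  rpkm <- make_rpkm(c(2, 4, 8, 0), 1e6)
  strata <- cpg_density_strata(grid, cpg, cov, rpkm)
  expect_equal(strata$n_windows, c(1L, 2L, 1L))
  expect_equal(sum(strata$n_windows), length(grid))
  expect_equal(strata$coverage_ratio, c(1, 0.5, 0))
  # mean density over covered windows of each class
  expect_equal(strata$mean_rpkm[1], 2)
  expect_equal(strata$mean_rpkm[2], 4)
  expect_true(is.na(strata$mean_rpkm[3]))
})

test_that("promoter summary reports covered count, fraction and mean RPKM", {
  grid <- make_windows(c(c1 = 1000), 100)
  cov <- covered_windows(make_counts(c(1, 1, 0, 0, 1, rep(0, 5))))
  rpkm <- make_rpkm(rep(3, 10), 1e6)
  promoters <- gr("c1", c(51, 601), c(150, 700),
                  gene_id = c("g1", "g2"))
  out <- promoter_rpkm_summary(rpkm, cov, promoters, grid)
  expect_equal(out$n_covered, 1L)
  expect_equal(out$fraction, 0.5)
  expect_equal(out$mean_rpkm, 3)  # uniform RPKM stays uniform

  zero <- promoter_rpkm_summary(rpkm, covered_windows(make_counts(rep(0, 10))),
                                promoters, grid)
  expect_equal(zero$n_covered, 0L)
  expect_true(is.na(zero$mean_rpkm))
})

test_that("metagene profiles have six strand-oriented bins with mirrored signal", {
  cs <- c(c1 = 10000)
  grid <- make_windows(cs, 100)
  rpkm_vals <- rep(1, length(grid))
  genes <- data.frame(gene_id = c("plus", "minus"), chrom = "c1",
                      strand = c("+", "-"), start = c(5000, 2000),
                      end = c(7000, 5000), tss = c(5000, 5000),
                      stringsAsFactors = FALSE)

  flat <- metagene_profile(make_rpkm(rpkm_vals), grid, genes)
  expect_equal(ncol(flat$per_gene), 6)
  expect_true(all(abs(flat$per_gene - 1) < 1e-12))

  expect_error(metagene_profile(make_rpkm(rpkm_vals), grid, genes, bin = 700),
               "divide")

  # single hot window just downstream of each TSS lands in bin 6 both ways:
  # plus gene (TSS 5000): bin 6 is [5000, 5499]; window [5001,5100] is inside
  hot_plus <- rpkm_vals; hot_plus[51] <- 101  # window [5001,5100]
  prof_p <- metagene_profile(make_rpkm(hot_plus), grid,
                             genes[genes$gene_id == "plus", ])
  expect_equal(as.integer(which.max(prof_p$per_gene[1, ])), 6L)

  # minus gene (TSS 5000): downstream is the lower-coordinate side,
  # bin 6 is [4501, 5000]; window [4601,4700] is inside
  hot_minus <- rpkm_vals; hot_minus[47] <- 101  # window [4601,4700]
  prof_m <- metagene_profile(make_rpkm(hot_minus), grid,
                             genes[genes$gene_id == "minus", ])
  expect_equal(as.integer(which.max(prof_m$per_gene[1, ])), 6L)

  # hand-computed bin value: 100 hot bases of 500 in the bin
  expect_equal(prof_m$per_gene[1, 6], (101 * 100 + 1 * 400) / 500)
})

test_that("bins clipped off-chromosome are NA and excluded from set means", {
  cs <- c(c1 = 3000)
  grid <- make_windows(cs, 100)
  genes <- data.frame(gene_id = "edge", chrom = "c1", strand = "+",
                      start = 1000, end = 2000, tss = 1000,
                      stringsAsFactors = FALSE)
  prof <- metagene_profile(make_rpkm(rep(2, length(grid))), grid, genes)
  # bins 1-3 cover [-1500, -1] and are entirely off-chromosome
  expect_true(all(is.na(prof$per_gene[1, 1:3])))
  expect_true(all(prof$per_gene[1, 4:6] == 2))
})
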