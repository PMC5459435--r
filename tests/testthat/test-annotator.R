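test_that("promoters sit upstream of the TSS, strand-aware and clipped", {
  cs <- c(c1 = 10000)
  plus <- data.frame(gene_id = "p", chrom = "c1", strand = "+",
                     start = 5001, end = 7000, tss = 5001)
  pr <- build_promoters(plus, cs)
  expect_equal(GenomicRanges::start(pr), 3001)
  expect_equal(GenomicRanges::end(pr), 5000)

  minus <- data.frame(gene_id = "m", chrom = "c1", strand = "-",
                      start = 3001, end = 5000, tss = 5000)
  pm <- build_promoters(minus, cs)
  expect_equal(GenomicRanges::start(pm), 5001)
  expect_equal(GenomicRanges::end(pm), 7000)

  near_edge <- data.frame(gene_id = "e", chrom = "c1", strand = "+",
                          start = 501, end = 900, tss = 501)
  pe <- build_promoters(near_edge, cs)
  expect_equal(GenomicRanges::start(pe), 1)
  expect_equal(GenomicRanges::end(pe), 500)

  bad <- plus; bad$strand <- "*"
  expect_error(build_promoters(bad, cs), "strand")
})

test_that("TTS regions extend downstream of the transcription end", {
  cs <- c(c1 = 10000)
  genes <- data.frame(gene_id = c("p", "m"), chrom = "c1",
                      strand = c("+", "-"), start = c(2001, 6001),
                      end = c(3000, 7000), tss = c(2001, 7000))
  tts <- build_tts_regions(genes, cs, width = 1000)
  expect_equal(GenomicRanges::start(tts), c(3001, 5001))
  expect_equal(GenomicRanges::end(tts), c(4000, 6000))
})

test_that("primary features follow the precedence with intergenic fallback", {
  features <- list(
    promoter = gr("c1", 1000, 1999, gene_id = "A"),
    utr5 = gr("c1", 2000, 2199, gene_id = "A"),
    exon = gr("c1", 2200, 2499, gene_id = "A"),
    utr3 = gr("c1", 3200, 3499, gene_id = "A"),
    tts = gr("c1", 3500, 4499, gene_id = "A"),
    intron = gr("c1", 2500, 3199, gene_id = "B"))
  # overlaps promoter of A and intron of B: promoter wins
  both <- gr("c1", c(1950, 9000, 2450), c(2600, 9100, 2550))
  out <- assign_primary_feature(both, features)
  expect_equal(as.character(out$primary_feature),
               c("promoter", "intergenic", "exon"))
  expect_equal(out$gene_ids[1], "A,B")
  expect_equal(out$gene_ids[2], "")
})

test_that("feature assignment agrees with a brute-force precedence oracle", {
  set.seed(55)
  for (i in 1:30) {
    mk <- function(n) {
      s <- sample(5000, n)
      data.frame(chrom = "c1", start = s,
                 end = s + sample(50:400, n, replace = TRUE))
    }
    feats_df <- list(promoter = mk(2), utr5 = mk(2), exon = mk(3),
                     utr3 = mk(2), tts = mk(2), intron = mk(3))
    features <- lapply(feats_df, function(df) {
      gr("c1", df$start, df$end, gene_id = "g")
    })
    s <- sample(5000, 10)
    regions <- gr("c1", s, s + 99)
    got <- as.character(assign_primary_feature(regions, features)$primary_feature)
    want <- vapply(seq_along(regions), function(j) {
      brute_primary_feature(list(chrom = "c1",
                                 start = GenomicRanges::start(regions)[j],
                                 end = GenomicRanges::end(regions)[j]),
                            feats_df)
    }, character(1))
    expect_equal(got, want)
  }
})

test_that("gene mapping is direction-aware with exact union arithmetic", {
  cs <- c(c1 = 20000)
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "c1",
                      strand = "+", start = c(3001, 3501, 12001),
                      end = c(5000, 6000, 14000),
                      tss = c(3001, 3501, 12001))
  promoters <- build_promoters(genes, cs)
  dhmrs <- data.frame(chrom = "c1",
                      start = c(4001, 12101, 13001),
                      end = c(4100, 12200, 13100),
                      direction = c("hyper", "hyper", "hypo"))
  tab <- dhmrs_to_genes(dhmrs, genes, promoters)
  counts <- attr(tab, "counts")
  # one DhMR spans both overlapping genes g1 and g2
  expect_setequal(tab$gene_id[tab$hyper], c("g1", "g2", "g3"))
  expect_setequal(tab$gene_id[tab$hypo], "g3")
  expect_equal(counts$n_hyper, 3L)
  expect_equal(counts$n_hypo, 1L)
  expect_equal(counts$n_union, 3L)
  expect_equal(counts$n_union,
               length(union(tab$gene_id[tab$hyper], tab$gene_id[tab$hypo])))

  none <- dhmrs_to_genes(dhmrs[0, ], genes, promoters)
  expect_equal(nrow(none), 0L)
})

test_that("imprinted promoters are flagged with parent-of-origin labels", {
  cs <- c(c1 = 30000)
  genes <- data.frame(gene_id = c("i1", "i2", "i3"), chrom = "c1",
                      strand = "+", start = c(5001, 15001, 25001),
                      end = c(6000, 16000, 26000),
                      tss = c(5001, 15001, 25001))
  promoters <- build_promoters(genes, cs)
  imprinted <- data.frame(gene_id = c("i1", "i2", "i3"),
                          origin = c("maternal", "paternal", "maternal"))
  dhmrs <- data.frame(chrom = "c1", start = 14801, end = 14900,
                      direction = "hyper")
  out <- flag_imprinted_promoters(dhmrs, promoters, imprinted)
  expect_equal(out$gene_id, "i2")
  expect_equal(out$origin, "paternal")

  empty <- flag_imprinted_promoters(dhmrs, promoters, imprinted[0, ])
  expect_equal(nrow(empty), 0L)

  with_unknown <- rbind(imprinted, data.frame(gene_id = "nope",
                                              origin = "maternal"))
  expect_warning(flag_imprinted_promoters(dhmrs, promoters, with_unknown),
                 "skipped")
})

test_that("repeat attribution is many-to-many with per-class densities", {
  repeats <- gr("c1", c(1, 501, 1001), c(400, 900, 1400),
                class = c("LINE", "SINE", "LINE"))
  dhmrs <- data.frame(chrom = "c1", start = c(301, 801), end = c(600, 1100),
                      direction = c("hyper", "hyper"))
  out <- dhmr_repeat_classes(dhmrs, repeats)
  expect_equal(out$n_dhmrs[out$class == "LINE"], 2L)
  expect_equal(out$n_dhmrs[out$class == "SINE"], 2L)
  expect_equal(out$class_bases[out$class == "LINE"], 800)
})
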