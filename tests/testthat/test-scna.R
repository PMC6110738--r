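mkseg <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(sample_id = r[[1]], chrom = r[[2]], start = as.numeric(r[[3]]),
               end = as.numeric(r[[4]]), value = as.numeric(r[[5]]),
               stringsAsFactors = FALSE)))
}

test_that("log2 ratios and discrete calls discretize per convention", {
  seg <- mkseg(list("S1", "chr1", 0, 1e4, 0.8),
               list("S1", "chr1", 1e4, 2e4, -0.05),
               list("S1", "chr1", 2e4, 3e4, -0.31))
  d <- discretizeSegments(seg)
  expect_equal(d$status, c(1L, 0L, -1L))
  segc <- mkseg(list("S2", "chr1", 0, 1e4, -2),
                list("S2", "chr1", 1e4, 2e4, 0),
                list("S2", "chr1", 2e4, 3e4, 1))
  expect_equal(discretizeSegments(segc)$status, c(-1L, 0L, 1L))
  mixed <- rbind(seg, segc)
  expect_error(discretizeSegments(mixed), "mixed call/ratio")
})

test_that("bin status follows the strict base-majority rule", {
  genome <- c(chr1 = 3e4)
  # amp covering 6,000 of the first 10 kb bin -> amp
  seg <- mkseg(list("S1", "chr1", 0, 6000, 0.8))
  bt <- binGenome(seg, genome)
  expect_equal(binStatus(bt)[, "S1"], c(1L, 0L, 0L))
  # exactly 5,000 amp / 5,000 neutral -> tie is not a majority
  seg2 <- mkseg(list("S1", "chr1", 0, 5000, 0.8))
  expect_equal(unname(binStatus(binGenome(seg2, genome))[1, "S1"]), 0L)
  # 5,001 wins
  seg3 <- mkseg(list("S1", "chr1", 0, 5001, 0.8))
  expect_equal(unname(binStatus(binGenome(seg3, genome))[1, "S1"]), 1L)
  # competing amp and del inside one bin: neither exceeds half
  seg4 <- mkseg(list("S1", "chr1", 0, 5000, 0.8),
                list("S1", "chr1", 5000, 10000, -0.8))
  expect_equal(unname(binStatus(binGenome(seg4, genome))[1, "S1"]), 0L)
  expect_error(binGenome(mkseg(list("S1", "chr1", 0, 4e4, 0.8)), genome),
               "beyond chromosome end")
})

test_that("binning matches the per-base oracle on random layouts", {
  genome <- c(chr1 = 1e6)
  th <- ergThresholds()
  set.seed(77)
  for (i in 1:12) {
    lay <- randomSegLayout(1e6)
    bt <- binGenome(lay, genome, th)
    oracle <- perBaseBinOracle(lay, 1e6, th$bin_width, th$majority_bases)
    expect_identical(unname(binStatus(bt)[, "S1"]), oracle)
  }
})

test_that("region frequency is the median over member-bin frequencies", {
  genome <- c(chr1 = 4e4)
  # two samples: S1 amp over bins 1-2, S2 amp over bin 1 only
  seg <- mkseg(list("S1", "chr1", 0, 2e4, 0.8),
               list("S2", "chr1", 0, 1e4, 0.8))
  bt <- binGenome(seg, genome)
  f <- regionFrequency(bt, c("S1", "S2"), "amp")
  expect_equal(f, c(1, 0.5, 0, 0))
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 4e4))
  S4Vectors::mcols(region)$name <- "chr1p"
  expect_equal(unname(regionFrequency(bt, c("S1", "S2"), "amp", region)),
               median(c(1, 0.5, 0, 0)))
  # all samples amp over the whole region -> frequency 1
  seg2 <- mkseg(list("S1", "chr1", 0, 4e4, 0.8),
                list("S2", "chr1", 0, 4e4, 0.8))
  bt2 <- binGenome(seg2, genome)
  expect_equal(unname(regionFrequency(bt2, c("S1", "S2"), "amp", region)), 1)
  # random tracks equal a recompute-from-scratch check
  set.seed(9)
  lay <- rbind(randomSegLayout(4e4, "S1"), randomSegLayout(4e4, "S2"))
  bt3 <- binGenome(lay[, 1:5], genome)
  manual <- rowMeans(binStatus(bt3) == 1L)
  expect_equal(regionFrequency(bt3, c("S1", "S2"), "amp"), manual)
})

test_that("region comparison flags frequency differences like the arm-level contrast", {
  # 296 negative / 201 positive samples; an arm deleted in 38.5% vs 19%
  np <- 201L; nn <- 296L
  genome <- c(chr8 = 1e5)
  region <- GenomicRanges::GRanges("chr8", IRanges::IRanges(1, 1e5))
  S4Vectors::mcols(region)$name <- "chr8q"
  S4Vectors::mcols(region)$level <- "arm"
  pos_ids <- sprintf("P%03d", 1:np); neg_ids <- sprintf("N%03d", 1:nn)
  carriers <- c(pos_ids[1:38], neg_ids[1:114])   # ~19% vs ~38.5%
  seg <- do.call(rbind, lapply(carriers, function(s)
    mkseg(list(s, "chr8", 0, 1e5, 0.9))))
  bt <- binGenome(seg, genome, sample_ids = c(pos_ids, neg_ids))
  groups <- setNames(rep(c("ERG_POS", "ERG_NEG"), c(np, nn)),
                     c(pos_ids, neg_ids))
  cmp <- compareRegions(bt, groups, region)
  amp_row <- cmp[cmp$status == "amp", ]
  expect_true(amp_row$significant)
  expect_equal(amp_row$freq_pos, 38 / 201)
  expect_equal(amp_row$freq_neg, 114 / 296)
  # equal high frequencies in both groups fail the p filter
  carriers2 <- c(pos_ids[1:80], neg_ids[1:118])  # ~40% both
  seg2 <- do.call(rbind, lapply(carriers2, function(s)
    mkseg(list(s, "chr8", 0, 1e5, 0.9))))
  bt2 <- binGenome(seg2, genome, sample_ids = c(pos_ids, neg_ids))
  cmp2 <- compareRegions(bt2, groups, region)
  expect_false(cmp2[cmp2$status == "amp", "significant"])
  # low equal frequencies fail the frequency floor
  carriers3 <- c(pos_ids[1:10], neg_ids[1:15])   # ~5%
  seg3 <- do.call(rbind, lapply(carriers3, function(s)
    mkseg(list(s, "chr8", 0, 1e5, 0.9))))
  bt3 <- binGenome(seg3, genome, sample_ids = c(pos_ids, neg_ids))
  cmp3 <- compareRegions(bt3, groups, region)
  expect_false(cmp3[cmp3$status == "amp", "significant"])
})
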