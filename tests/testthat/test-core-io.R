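test_that("SEG input converts 1-based inclusive to half-open and back", {
  d <- withr::local_tempdir()
  writeLines(c("sample_id\tchrom\tstart\tend\tvalue",
               "S1\tchr8\t1\t1000000\t0.8"),
             file.path(d, "seg.tsv"))
  seg <- readSeg(file.path(d, "seg.tsv"))
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 0)
  expect_equal(seg$end, 1e6)
  expect_equal(seg$end - seg$start, 1e6)   # half-open length arithmetic
  expect_equal(seg$value, 0.8)
  co <- ErgCohort(clinical = tinyClinical("S1"), segments = seg)
  writeCohortDir(co, file.path(d, "out"))
  again <- readSeg(file.path(d, "out", "segments.seg"))
  expect_equal(again, seg)
})

test_that("malformed coordinates name the file and line", {
  d <- withr::local_tempdir()
  writeLines(c("sample_id\tchrom\tstart\tend\tvalue",
               "S1\tchr1\t100\t50\t0.3"),
             file.path(d, "bad.seg"))
  expect_error(readSeg(file.path(d, "bad.seg")), "bad.seg.*line 1")
})

test_that("a minimal cohort may have empty omics layers", {
  d <- withr::local_tempdir()
  co <- ErgCohort(clinical = tinyClinical())
  writeCohortDir(co, d)
  back <- readCohortDir(d)
  expect_equal(nrow(clinical(back)), 3L)
  expect_equal(nrow(fusionCalls(back)), 0L)
  expect_equal(ncol(exprCounts(back)), 0L)
})

test_that("omics samples missing from the clinical table are reported by ID", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("G1", "G2"), c("S1", "GHOST")))
  expect_error(ErgCohort(clinical = tinyClinical(), expression = m),
               "GHOST")
  beta <- matrix(c(0.1, 1.2), 1, 2,
                 dimnames = list("p1", c("S1", "S2")))
  expect_error(ErgCohort(clinical = tinyClinical(), methylation = beta),
               "beta outside")
})

test_that("full simulated cohort round-trips through the directory format", {
  cfg <- simConfig(n_pos = 6, n_neg = 8, n_normal = 3,
                   n_background_genes = 5, seed = 99)
  sim <- simulateCohort(cfg)
  d <- withr::local_tempdir()
  writeCohortDir(sim$cohort, d)
  back <- readCohortDir(d)
  expect_equal(clinical(back)$sample_id, clinical(sim$cohort)$sample_id)
  expect_equal(clinical(back)$group, clinical(sim$cohort)$group)
  expect_equal(segTable(back)$start, segTable(sim$cohort)$start)
  expect_equal(segTable(back)$value, segTable(sim$cohort)$value)
  expect_equal(exprCounts(back), exprCounts(sim$cohort))
  expect_equal(methBeta(back), methBeta(sim$cohort), tolerance = 1e-8)
  expect_equal(sort(fusionCalls(back)$sample_id),
               sort(fusionCalls(sim$cohort)$sample_id))
  expect_equal(mutationCalls(back)[order(mutationCalls(back)$sample_id,
                                         mutationCalls(back)$gene), ],
               mutationCalls(sim$cohort)[order(
                 mutationCalls(sim$cohort)$sample_id,
                 mutationCalls(sim$cohort)$gene), ],
               ignore_attr = TRUE)
  expect_equal(S4Vectors::mcols(geneAnno(back))$symbol,
               S4Vectors::mcols(geneAnno(sim$cohort))$symbol)
  expect_equal(GenomicRanges::start(geneAnno(back)),
               GenomicRanges::start(geneAnno(sim$cohort)))
})

test_that("comparison tables round-trip with deterministic column order", {
  d <- withr::local_tempdir()
  cmp <- data.frame(item = c("A", "B"), freq_pos = c(0.1, 0.2),
                    freq_neg = c(0.3, 0.25), delta = c(0.2, 0.05),
                    test_used = "chi2_yates", p = c(0.01, 0.5),
                    significant = c(TRUE, FALSE), stringsAsFactors = FALSE)
  f <- file.path(d, "cmp.tsv")
  writeComparison(cmp, f)
  expect_equal(readComparison(f), cmp)
  empty <- cmp[0, ]
  writeComparison(empty, f)
  back <- readComparison(f)
  expect_equal(nrow(back), 0L)
  expect_equal(names(back), names(cmp))
})

test_that("MAF variant classes map onto the nonsilent/silent dichotomy", {
  d <- withr::local_tempdir()
  writeLines(c("Hugo_Symbol\tTumor_Sample_Barcode\tVariant_Classification",
               "TP53\tS1\tMissense_Mutation",
               "TP53\tS2\tSilent",
               "SPOP\tS3\tFrame_Shift_Del"),
             file.path(d, "mutations.tsv"))
  write.table(tinyClinical(), file.path(d, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  co <- readCohortDir(d)
  mut <- mutationCalls(co)
  expect_equal(mut$variant_class, c("nonsilent", "silent", "nonsilent"))
})

test_that("GMT pathways parse name, description and members", {
  d <- withr::local_tempdir()
  writeLines(c("AR\tandrogen axis\tAR\tNCOA2\tCDK6",
               "NOTCH\tnotch signaling\tDVL2\tHDAC2"),
             file.path(d, "sets.gmt"))
  gmt <- readGmt(file.path(d, "sets.gmt"))
  expect_named(gmt, c("AR", "NOTCH"))
  expect_equal(gmt$AR, c("AR", "NCOA2", "CDK6"))
})

test_that("threshold configuration validates its domains", {
  expect_equal(ergThresholds()$bin_width, 10000L)
  expect_equal(ergThresholds(de_p = 0.01)$de_p, 0.01)
  expect_error(ergThresholds(nope = 1), "unknown threshold")
  expect_error(ergThresholds(de_p = 2), "lie in")
  expect_error(ergThresholds(common_scna_freq = 0), "lie in")
})
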