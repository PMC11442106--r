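test_that("readBsaVcf returns coordinate-sorted biallelic records with depths", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeFixtureVcf(vcf, list(
    c("chr2", "500", "A", "T", "60,40", "100,0", "50,10", "70,5"),
    c("chr1", "300", "A", "ACG", "60,40", "100,0", "50,10", "70,5"),
    c("chr1", "100", "G", "C", "30,10", "90,0", "40,20", "60,8")))
  x <- readBsaVcf(vcf, fixtureSampleMap)
  expect_equal(nrow(x), 3L)
  expect_equal(GenomicRanges::start(x), c(100L, 300L, 500L))
  expect_equal(as.character(GenomeInfoDb::seqnames(x)),
               c("chr1", "chr1", "chr2"))
  expect_equal(unname(refDepth(x)[1, ]), c(30L, 90L, 40L, 60L))
  expect_equal(unname(altDepth(x)[1, ]), c(10L, 0L, 20L, 8L))
  ## ref "A" alt "ACG" has variant length 2
  expect_equal(variantLength(x), c(0L, 2L, 0L))
})

test_that("multiallelic sites follow the configured policy", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeFixtureVcf(vcf, list(
    c("chr1", "100", "A", "T", "60,40", "100,0", "50,10", "70,5"),
    c("chr1", "200", "A", "T,G", "60,30,10", "100,0,0", "50,5,5", "70,2,3"),
    c("chr1", "300", "C", "G", "55,45", "95,5", "45,15", "65,10")))
  xd <- readBsaVcf(vcf, fixtureSampleMap, multiallelic = "drop")
  expect_equal(nrow(xd), 2L)
  expect_false(200L %in% GenomicRanges::start(xd))

  ## split must agree with hand-splitting the site into two biallelic records
  xs <- readBsaVcf(vcf, fixtureSampleMap, multiallelic = "split")
  expect_equal(nrow(xs), 4L)
  at200 <- which(GenomicRanges::start(xs) == 200L)
  expect_equal(length(at200), 2L)
  expect_setequal(rowDat(xs)$alt[at200], c("T", "G"))
  iT <- at200[rowDat(xs)$alt[at200] == "T"]
  iG <- at200[rowDat(xs)$alt[at200] == "G"]
  expect_equal(unname(altDepth(xs)[iT, ]), c(30L, 0L, 5L, 2L))
  expect_equal(unname(altDepth(xs)[iG, ]), c(10L, 0L, 5L, 3L))
  expect_equal(unname(refDepth(xs)[iT, ]), c(60L, 100L, 50L, 70L))
})

test_that("missing sample names are a fatal configuration error", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeFixtureVcf(vcf, list(
    c("chr1", "100", "A", "T", "60,40", "100,0", "50,10", "70,5")))
  bad <- fixtureSampleMap
  bad["P2"] <- "nope"
  expect_error(readBsaVcf(vcf, bad), "not found")
  expect_error(readBsaVcf(vcf, c(P1 = "P1s")), "sampleMap")
})

test_that("filterVariants enforces per-role depth and indel-length bounds", {
  ## P1 depth 49 vs 50 at the boundary; all-depth-50 retained
  x <- makeVS("chr1", c(100, 200, 300),
              refD = rbind(c(9, 60, 60, 60), c(10, 60, 60, 60),
                           c(25, 25, 25, 25)),
              altD = rbind(c(40, 40, 40, 40), c(40, 40, 40, 40),
                           c(25, 25, 25, 25)))
  f <- filterVariants(x, minDepth = 50)
  expect_equal(GenomicRanges::start(f), c(200L, 300L))

  ## indel length 71 retained, 72 removed (indels must be < 72 bp)
  long71 <- paste(rep("A", 72), collapse = "")
  long72 <- paste(rep("A", 73), collapse = "")
  y <- makeVS("chr1", c(10, 20), refD = 100, altD = 100, ref = "A",
              alt = c(long71, long72))
  fy <- filterVariants(y)
  expect_equal(GenomicRanges::start(fy), 10L)

  ## idempotent and order-preserving
  x2 <- filterVariants(x, minDepth = 50)
  expect_identical(GenomicRanges::start(filterVariants(x2, minDepth = 50)),
                   GenomicRanges::start(x2))
})

test_that("scored TSV round-trips numeric fields to 4 decimals", {
  x <- makeVS("chr1", c(100, 200), refD = c(118, 118, 118, 118),
              altD = c(89, 89, 89, 89))
  x <- classifyVariants(x, "P1", donorIndexRange = c(0, 1),
                        maxOtherAltReads = 1000)
  x <- scoreVariants(x, nLow = 10, nHigh = 21, replicates = 1000, seed = 1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeScoredTsv(x, tsv)
  df <- read.delim(tsv)
  expect_equal(nrow(df), 2L)
  expect_equal(colnames(df),
               c("chrom", "pos", "donor", "plexity", "idx_low", "idx_high",
                 "delta", "p_value", "sig95", "sig99"))
  rd <- rowDat(x)
  expect_true(all(abs(df$idx_low - rd$idxLow) <= 1e-4))
  expect_true(all(abs(df$delta - rd$delta) <= 1e-4))
  expect_true(all(abs(df$p_value - rd$p) <= 1e-4))
  expect_identical(df$donor, rd$donor)
  ## 89 alt / 118 ref prints as 0.4300
  expect_true(any(grepl("0.4300", readLines(tsv), fixed = TRUE)))

  ## empty input gives a header-only file
  e <- scoreVariants(classifyVariants(makeVS("chr1", integer(0),
                                             refD = integer(0),
                                             altD = integer(0)), "P1"),
                     nLow = 10, nHigh = 21, replicates = 1000, seed = 1)
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  writeScoredTsv(e, tsv2)
  expect_equal(length(readLines(tsv2)), 1L)
})

test_that("chromosome-length tables read with or without header", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000000", "chr2\t500000"), f)
  cl <- readChromLengths(f)
  expect_equal(cl, c(chr1 = 1e6, chr2 = 5e5))
  writeLines(c("name\tlength", "chr1\t1000000"), f)
  expect_equal(readChromLengths(f), c(chr1 = 1e6))
})
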