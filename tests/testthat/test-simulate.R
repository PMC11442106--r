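test_that("cross configuration is validated", {
  expect_error(crossConfig(c(chr1 = 1e6), plexityMix = c(0.5, 0.2, 0.2)),
               "plexityMix")
  expect_error(crossConfig(c(chr1 = 1e6), bulkLowN = 80, bulkHighN = 80,
                           nProgeny = 126))
  expect_error(crossConfig(c(chr1 = 1e6),
                           qtls = data.frame(chrom = "chr1", pos = 2e6,
                                             donor = "P1", effect = 1)))
  expect_s3_class(crossConfig(c(chr1 = 1e6)), "CrossConfig")
})

test_that("segregation ratios match plexity expectations", {
  cfg <- crossConfig(c(chr1 = 2e6), variantDensity = 1 / 2000,
                     nProgeny = 1000, plexityMix = c(1, 0, 0), seed = 2)
  cr <- makeCross(cfg)
  d <- progenyDoses(cr, rows = 1:5)
  ## simplex carriers segregate 1:1
  expect_true(all(abs(rowMeans(d > 0) - 0.5) < 0.05))

  cfg3 <- crossConfig(c(chr1 = 2e6), variantDensity = 1 / 5000,
                      nProgeny = 1000, plexityMix = c(0, 0, 1), seed = 3)
  d3 <- progenyDoses(makeCross(cfg3), rows = 1:5)
  ## triplex carrier fraction 1 - C(3,3)/C(6,3) = 0.95
  expect_true(all(abs(rowMeans(d3 > 0) - 0.95) < 0.02))

  ## recombination mode preserves the hypergeometric duplex dose law
  cfgR <- crossConfig(c(chr1 = 2e6), variantDensity = 1 / 4000,
                      nProgeny = 2000, plexityMix = c(0, 1, 0),
                      recombination = TRUE, seed = 4)
  dR <- progenyDoses(makeCross(cfgR), rows = 1)
  frac <- table(factor(dR, levels = 0:2)) / length(dR)
  expect_equal(as.numeric(frac), c(0.2, 0.6, 0.2), tolerance = 0.04)

  ## zero variants: empty cross without error
  cfg0 <- crossConfig(c(chr1 = 1e4), variantDensity = 1e-9, seed = 5)
  expect_equal(nrow(makeCross(cfg0)$variants), 0L)
})

test_that("phenotypes are additive in QTL doses", {
  cfg <- crossConfig(c(chr1 = 1e6), variantDensity = 1 / 5e5, nProgeny = 400,
                     seed = 6)
  expect_true(all(assignPhenotypes(makeCross(cfg)) == 0))

  q1 <- data.frame(chrom = "chr1", pos = 5e5, donor = "P1", effect = 10)
  cfg1 <- crossConfig(c(chr1 = 1e6), variantDensity = 1 / 5e5,
                      nProgeny = 1000, qtls = q1, seed = 6)
  ph <- assignPhenotypes(makeCross(cfg1))
  expect_setequal(unique(ph), c(0, 10))
  expect_lt(abs(mean(ph > 0) - 0.5), 0.05)

  q2 <- rbind(q1, data.frame(chrom = "chr1", pos = 8e5, donor = "P2",
                             effect = 3))
  cfg2 <- crossConfig(c(chr1 = 1e6), variantDensity = 1 / 5e5,
                      nProgeny = 1000, qtls = q2, seed = 6)
  ph2 <- assignPhenotypes(makeCross(cfg2))
  expect_true(all(ph2 %in% c(0, 3, 10, 13)))
  expect_equal(length(unique(ph2)), 4L)
})

test_that("bulk selection takes extreme ranks deterministically", {
  b <- makeBulks(1:126, 10, 21)
  expect_equal(b$low, 1:10)
  expect_equal(b$high, 106:126)
  ## complete ties still give disjoint, index-deterministic bulks
  b2 <- makeBulks(rep(0, 126), 10, 21)
  expect_equal(b2$low, 1:10)
  expect_equal(b2$high, 106:126)
  expect_length(intersect(b2$low, b2$high), 0L)
  ## partition when sizes cover all progeny
  b3 <- makeBulks(rnorm(31), 10, 21)
  expect_setequal(c(b3$low, b3$high), 1:31)
})

test_that("emitted VCF round-trips depths exactly and honours the model", {
  q <- data.frame(chrom = "chr1", pos = 5e5, donor = "P1", effect = 5)
  cfg <- crossConfig(c(chr1 = 1e6), variantDensity = 1 / 2000, qtls = q,
                     plexityMix = c(1, 0, 0), seed = 8)
  sim <- simulateBsaCross(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  truth <- withr::local_tempfile(fileext = ".tsv")
  cl <- withr::local_tempfile(fileext = ".tsv")
  writeCrossVcf(sim, vcf, truthPath = truth, chromLengthsPath = cl)
  x <- readBsaVcf(vcf, c(P1 = "P1", P2 = "P2", BULK_LOW = "BULK_LOW",
                         BULK_HIGH = "BULK_HIGH"))
  expect_equal(nrow(x), nrow(sim$variantSet))
  expect_equal(refDepth(x), refDepth(sim$variantSet))
  expect_equal(altDepth(x), altDepth(sim$variantSet))
  expect_equal(readChromLengths(cl), c(chr1 = 1e6))
  tt <- read.delim(truth)
  expect_equal(nrow(tt), nrow(x))
  expect_true(any(tt$linked_qtl))

  ## deep coverage: donor parental fraction ~ 1/6; unlinked bulk index ~ 0.083
  cfgD <- crossConfig(c(chr1 = 5e5), variantDensity = 1 / 500,
                      nProgeny = 400, bulkLowN = 150, bulkHighN = 150,
                      plexityMix = c(1, 0, 0), depthMean = 1e5, seed = 9)
  simD <- simulateBsaCross(cfgD)
  fr <- snpIndex(refDepth(simD$variantSet), altDepth(simD$variantSet))
  donorCol <- ifelse(simD$truth$donor == "P1", 1L, 2L)
  pf <- fr[cbind(seq_len(nrow(fr)), donorCol)]
  expect_equal(mean(pf), 1 / 6, tolerance = 0.01)
  expect_equal(mean(fr[, 3]), 1 / 12, tolerance = 0.01)
  expect_equal(mean(fr[, 4]), 1 / 12, tolerance = 0.01)
})

test_that("phenotype noise degrades the delta signal at the QTL", {
  deltas <- vapply(c(0, 5, 20), function(ns) {
    q <- data.frame(chrom = "chr1", pos = 5e5, donor = "P1", effect = 10)
    cfg <- crossConfig(c(chr1 = 1e6), variantDensity = 1 / 1000, qtls = q,
                       plexityMix = c(1, 0, 0), phenotypeNoiseSd = ns,
                       seed = 10)
    sim <- simulateBsaCross(cfg)
    tr <- sim$truth
    idx <- snpIndex(refDepth(sim$variantSet), altDepth(sim$variantSet))
    mean((idx[tr$linked_qtl, 4] - idx[tr$linked_qtl, 3]))
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
  expect_equal(deltas[1], 1 / 6, tolerance = 0.02)
})
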