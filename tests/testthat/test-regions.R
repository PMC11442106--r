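test_that("count criterion calls one-directional runs over the span minimum", {
  ## 101 windows span (100*20kb + 100kb) = 2.1 Mb
  w <- makeWindows(101, up95 = 25, down95 = 0)
  iv <- callCountCriterion(w)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$direction, "up")
  expect_equal(iv$start, 1)
  expect_equal(iv$end, w$end[101])

  ## an interior bidirectional window voids the interval (default strict mode)
  w2 <- w
  w2$count95_down[50] <- 25L
  expect_equal(nrow(callCountCriterion(w2)), 0L)

  ## span below 2 Mb is not called: 91 windows -> 1.9 Mb
  w3 <- makeWindows(91, up95 = 25)
  expect_equal(nrow(callCountCriterion(w3)), 0L)

  ## counts at the threshold (not exceeding) do not qualify
  w4 <- makeWindows(101, up95 = 20)
  expect_equal(nrow(callCountCriterion(w4)), 0L)
})

test_that("count criterion is sign-symmetric", {
  set.seed(8)
  w <- makeWindows(300)
  w$count95_up <- rpois(300, 3) + ifelse(seq_len(300) %in% 100:220, 30L, 0L)
  w$count95_down <- rpois(300, 2)
  up <- callCountCriterion(w)
  flipped <- w
  flipped$count95_up <- w$count95_down
  flipped$count95_down <- w$count95_up
  dn <- callCountCriterion(flipped)
  expect_equal(nrow(up), nrow(dn))
  expect_equal(up$start, dn$start)
  expect_equal(up$end, dn$end)
  expect_true(all(up$direction == "up") && all(dn$direction == "down"))
})

test_that("region mode vetoes only opposite clusters that span the minimum", {
  ## isolated opposite windows inside a long run do not void it in region mode
  w <- makeWindows(150, up99 = 30)
  w$count99_down[c(60, 80)] <- 30L
  expect_equal(nrow(callCountCriterion(w, level = "99", mode = "strict")), 0L)
  rg <- callCountCriterion(w, level = "99", mode = "region")
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$direction, "up")
  ## but a sustained opposite cluster overlapping the run does void it
  w2 <- makeWindows(300, up99 = 30)
  w2$count99_down[100:220] <- 30L
  expect_equal(nrow(callCountCriterion(w2, level = "99", mode = "region")), 0L)
})

test_that("zero-cluster criterion needs abundance, dominance and span", {
  w <- makeWindows(110, zl = 15, zh = 1)
  iv <- callZeroClusterCriterion(w)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$bulk, "low")

  ## no dominance: 15 vs 12 zeros
  w2 <- makeWindows(110, zl = 15, zh = 12)
  expect_equal(nrow(callZeroClusterCriterion(w2)), 0L)

  ## all zero counts zero
  expect_equal(nrow(callZeroClusterCriterion(makeWindows(110))), 0L)

  ## short gaps are tolerated up to the qualifying fraction
  w3 <- makeWindows(120, zl = 15, zh = 1)
  w3$zeros_low[c(40, 40 + 10)] <- 2L
  expect_equal(nrow(callZeroClusterCriterion(w3)), 1L)
})

test_that("regions require overlap with polarity-consistent zero clusters", {
  ci <- data.frame(chrom = "chr1", start = 2e6, end = 6e6, direction = "up",
                   n_windows = 200L, stringsAsFactors = FALSE)
  ziLow <- data.frame(chrom = "chr1", start = 3e6, end = 5e6, bulk = "low",
                      n_windows = 100L, stringsAsFactors = FALSE)
  w <- makeWindows(400, up95 = 25, zl = 15, delta = 0.1)
  reg <- callQtlRegions(ci, ziLow, w)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 3e6)
  expect_equal(reg$end, 5e6)
  expect_equal(reg$direction, "up")
  expect_equal(reg$zero_cluster_bulk, "low")
  expect_true(reg$criterion1_met && reg$criterion2_met)
  ## peak window is the member window with max |mean_delta|
  expect_equal(reg$peak_window_start,
               w$start[which.max(abs(w$mean_delta) *
                                   (w$start <= 5e6 & w$end >= 3e6))])

  ## different chromosomes never intersect
  ziChr2 <- ziLow; ziChr2$chrom <- "chr2"
  expect_equal(nrow(callQtlRegions(ci, ziChr2, w)), 0L)

  ## up interval over a HIGH-bulk zero cluster is polarity-inconsistent
  ziHigh <- ziLow; ziHigh$bulk <- "high"
  expect_equal(nrow(callQtlRegions(ci, ziHigh, w)), 0L)
})

test_that("marker candidates obey tolerances, polarity and depth ranking", {
  reg <- data.frame(chrom = "chr1", start = 1000, end = 9000,
                    direction = "up", zero_cluster_bulk = "low",
                    stringsAsFactors = FALSE)
  dep <- rbind(c(100, 100, 200, 200),  # idx_low 0.00, idx_high 0.165: marker
               c(100, 100, 200, 200),  # idx_low 0.05: rejected
               c(100, 100, 100, 100))  # like row 1, lower bulk depth
  alt <- rbind(c(20, 0, 0, 33), c(20, 0, 10, 33), c(20, 0, 0, 17))
  x <- makeVS("chr1", c(2000, 3000, 4000), refD = dep - alt, altD = alt)
  x <- classifyVariants(x, "P1")
  sc <- scoreVariants(x, nLow = 10, nHigh = 21, replicates = 1000, seed = 1)
  mk <- selectMarkerCandidates(sc, reg)
  expect_equal(nrow(mk), 2L)
  expect_false(3000 %in% mk$pos)
  ## deeper bulk coverage ranks first
  expect_equal(mk$pos, c(2000, 4000))
  expect_equal(mk$rank, c(1L, 2L))
  ## topK truncates
  expect_equal(nrow(selectMarkerCandidates(sc, reg, topK = 1)), 1L)
  ## nothing inside region
  regFar <- reg; regFar$start <- 1e6; regFar$end <- 2e6
  expect_equal(nrow(selectMarkerCandidates(sc, regFar)), 0L)
})

test_that("overlapping called regions merge into one", {
  ci <- data.frame(chrom = "chr1", start = c(2e6, 4e6), end = c(5e6, 8e6),
                   direction = "up", n_windows = 100L,
                   stringsAsFactors = FALSE)
  zi <- data.frame(chrom = "chr1", start = 3e6, end = 7e6, bulk = "low",
                   n_windows = 100L, stringsAsFactors = FALSE)
  w <- makeWindows(450, delta = 0.1)
  reg <- callQtlRegions(ci, zi, w)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start, 3e6)
  expect_equal(reg$end, 7e6)
})
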