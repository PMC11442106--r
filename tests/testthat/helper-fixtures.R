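roles <- c("P1", "P2", "BULK_LOW", "BULK_HIGH")

## BsaVariantSet from per-role depth vectors (recycled to length of pos)
makeVS <- function(chrom, pos, refD, altD, ref = "A", alt = "T") {
  n <- length(pos)
  rmat <- matrix(as.integer(refD), n, 4, byrow = length(refD) == 4,
                 dimnames = list(NULL, roles))
  amat <- matrix(as.integer(altD), n, 4, byrow = length(altD) == 4,
                 dimnames = list(NULL, roles))
  gr <- GenomicRanges::GRanges(rep_len(chrom, n),
                               IRanges::IRanges(pos, width = 1),
                               ref = rep_len(ref, n), alt = rep_len(alt, n))
  BsaVariantSet(gr, rmat, amat)
}

rowDat <- function(x) SummarizedExperiment::rowData(x)

## write a small VCF with AD fields; rows = list of character vectors
## c(chrom, pos, ref, alt, AD_P1, AD_P2, AD_LOW, AD_HIGH)
writeFixtureVcf <- function(path, rows,
                            samples = c("P1s", "P2s", "BLs", "BHs"),
                            contigs = c(chr1 = 1000000, chr2 = 1000000)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(rows, function(r)
    paste(c(r[1], r[2], ".", r[3], r[4], ".", "PASS", ".", "AD",
            r[5], r[6], r[7], r[8]), collapse = "\t"), character(1))
  writeLines(c(hdr, body), path)
  path
}

fixtureSampleMap <- c(P1 = "P1s", P2 = "P2s", BULK_LOW = "BLs",
                      BULK_HIGH = "BHs")

## synthetic window table builder for region-calling tests
makeWindows <- function(n, chrom = "chr1", step = 20000, window = 100000,
                        up95 = 0, down95 = 0, up99 = 0, down99 = 0,
                        zl = 0, zh = 0, delta = 0) {
  starts <- seq(1, by = step, length.out = n)
  data.frame(chrom = chrom, start = starts, end = starts + window - 1,
             n_variants = 50L,
             mean_idx_low = 0.08, mean_idx_high = 0.08,
             mean_delta = rep_len(delta, n), mean_neglog10p = 0.5,
             count95_up = rep_len(as.integer(up95), n),
             count95_down = rep_len(as.integer(down95), n),
             count99_up = rep_len(as.integer(up99), n),
             count99_down = rep_len(as.integer(down99), n),
             zeros_low = rep_len(as.integer(zl), n),
             zeros_high = rep_len(as.integer(zh), n),
             stringsAsFactors = FALSE)
}

## shared study settings for end-to-end simulator-based checks
studyAnalysis <- function(scored, chromLengths) {
  w <- slidingWindowScan(scored, chromLengths)
  callQtlRegions(callCountCriterion(w, level = "99", mode = "region"),
                 callZeroClusterCriterion(w, zeroMin = 5, dominanceRatio = 3),
                 w)
}
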