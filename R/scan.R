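#' Score classified variants against the no-QTL null
#'
#' Computes, per variant, the SNP-index of each bulk, the delta SNP-index
#' (high minus low, so positive delta means the donor allele increases the
#' trait), an empirical two-sided P value and 95\%/99\% significance flags
#' from the null simulation at that variant's exact (low, high) depth pair,
#' and zero-index flags. Null distributions are cached per depth pair, with
#' per-pair RNG streams derived deterministically from \code{seed} so results
#' do not depend on variant order.
#'
#' @param x a classified \code{\linkS4class{BsaVariantSet}} (all rows share
#'   one donor and plexity; see \code{\link{classifyVariants}}).
#' @param nLow,nHigh bulk sizes (individuals), e.g. 10 and 21.
#' @param ploidy even integer (default 6).
#' @param replicates null-simulation replicates per depth pair (default
#'   10000).
#' @param seed global seed for the null simulation streams.
#' @return \code{x} with \code{rowData} columns \code{idxLow}, \code{idxHigh},
#'   \code{delta}, \code{p}, \code{sig95}, \code{sig99}, \code{zeroInLow},
#'   \code{zeroInHigh}, plus the per-variant null thresholds \code{lower95},
#'   \code{upper95}, \code{lower99}, \code{upper99}.
#' @export
scoreVariants <- function(x, nLow, nHigh, ploidy = 6,
                          replicates = 10000, seed = 1) {
  rd <- SummarizedExperiment::rowData(x)
  if (nrow(x) > 0L && !"plexity" %in% colnames(rd))
    stop("variants are not classified; run classifyVariants() first")
  n <- nrow(x)
  if (n == 0L) {
    for (col in c("idxLow", "idxHigh", "delta", "p"))
      rd[[col]] <- numeric(0)
    for (col in c("sig95", "sig99", "zeroInLow", "zeroInHigh"))
      rd[[col]] <- logical(0)
    for (col in c("lower95", "upper95", "lower99", "upper99"))
      rd[[col]] <- numeric(0)
    SummarizedExperiment::rowData(x) <- rd
    return(x)
  }
  plexity <- rd$plexity[1L]
  td <- totalDepth(x)
  ad <- altDepth(x)
  if (any(td[, c("BULK_LOW", "BULK_HIGH")] < 1))
    stop("zero bulk depth after filtering; cannot compute SNP-index")
  idxLow <- ad[, "BULK_LOW"] / td[, "BULK_LOW"]
  idxHigh <- ad[, "BULK_HIGH"] / td[, "BULK_HIGH"]
  delta <- idxHigh - idxLow

  cache <- .nullCache()
  keyLow <- td[, "BULK_LOW"]
  keyHigh <- td[, "BULK_HIGH"]
  key <- paste0(keyLow, ":", keyHigh)
  p <- numeric(n); s95 <- logical(n); s99 <- logical(n)
  th <- matrix(NA_real_, n, 4L,
               dimnames = list(NULL, c("lower95", "upper95", "lower99", "upper99")))
  for (k in unique(key)) {
    sel <- which(key == k)
    i <- sel[1L]
    nd <- .cachedNull(cache, keyLow[i], keyHigh[i], nLow, nHigh,
                      ploidy, plexity, replicates, seed)
    res <- empiricalPValue(delta[sel], nd)
    p[sel] <- res$p; s95[sel] <- res$sig95; s99[sel] <- res$sig99
    th[sel, ] <- matrix(as.numeric(nd@thresholds), length(sel), 4L, byrow = TRUE)
  }
  rd$idxLow <- idxLow; rd$idxHigh <- idxHigh; rd$delta <- delta
  rd$p <- p; rd$sig95 <- s95; rd$sig99 <- s99
  rd$zeroInLow <- idxLow == 0; rd$zeroInHigh <- idxHigh == 0
  rd$lower95 <- th[, 1L]; rd$upper95 <- th[, 2L]
  rd$lower99 <- th[, 3L]; rd$upper99 <- th[, 4L]
  SummarizedExperiment::rowData(x) <- rd
  x
}

#' Sliding-window genome scan
#'
#' Aggregates scored variants into windows of \code{windowBp} starting at
#' 1, 1 + stepBp, 1 + 2*stepBp, ... per chromosome (1-based inclusive
#' intervals; the last window is clipped at the chromosome end). A variant at
#' position p belongs to every window whose interval contains p. Windows with
#' no variants report \code{NA} means and zero counts. Directional QTL-variant
#' counts use strict delta sign: \code{count95_up} counts variants with
#' \code{sig95} and \code{delta > 0}, etc.
#'
#' @param x a scored \code{\linkS4class{BsaVariantSet}}, sorted by
#'   (chromosome, position).
#' @param chromLengths named vector of chromosome lengths in bp (see
#'   \code{\link{readChromLengths}}); chromosomes absent from \code{x} still
#'   yield (empty) windows.
#' @param windowBp window size in bp (default 100000).
#' @param stepBp window increment in bp (default 20000).
#' @return \code{data.frame} with one row per window: \code{chrom},
#'   \code{start}, \code{end}, \code{n_variants}, \code{mean_idx_low},
#'   \code{mean_idx_high}, \code{mean_delta}, \code{mean_neglog10p},
#'   \code{count95_up}, \code{count95_down}, \code{count99_up},
#'   \code{count99_down}, \code{zeros_low}, \code{zeros_high}.
#' @export
slidingWindowScan <- function(x, chromLengths, windowBp = 100000,
                              stepBp = 20000) {
  stopifnot(windowBp >= 1, stepBp >= 1, length(chromLengths) >= 1)
  rd <- SummarizedExperiment::rowData(x)
  if (nrow(x) > 0L && !"delta" %in% colnames(rd))
    stop("variants are not scored; run scoreVariants() first")
  chrom <- as.character(GenomeInfoDb::seqnames(x))
  pos <- GenomicRanges::start(x)
  o <- order(match(chrom, names(chromLengths)), pos)
  if (!identical(o, seq_along(o)))
    stop("variants must be sorted by (chromosome, position)")
  if (!all(chrom %in% names(chromLengths)))
    stop("variant chromosome(s) missing from chromLengths")

  out <- lapply(names(chromLengths), function(cn) {
    len <- chromLengths[[cn]]
    starts <- seq(1, len, by = stepBp)
    ends <- pmin(starts + windowBp - 1, len)
    nw <- length(starts)
    sel <- chrom == cn
    df <- data.frame(chrom = cn, start = starts, end = ends,
                     n_variants = 0L,
                     mean_idx_low = NA_real_, mean_idx_high = NA_real_,
                     mean_delta = NA_real_, mean_neglog10p = NA_real_,
                     count95_up = 0L, count95_down = 0L,
                     count99_up = 0L, count99_down = 0L,
                     zeros_low = 0L, zeros_high = 0L,
                     stringsAsFactors = FALSE)
    if (!any(sel)) return(df)
    p <- pos[sel]
    v <- rd[sel, , drop = FALSE]
    up95 <- v$sig95 & v$delta > 0
    dn95 <- v$sig95 & v$delta < 0
    up99 <- v$sig99 & v$delta > 0
    dn99 <- v$sig99 & v$delta < 0
    nlp <- -log10(v$p)
    maxOff <- ceiling(windowBp / stepBp) - 1L
    last <- (p - 1) %/% stepBp + 1  # last window index whose start <= p
    for (off in 0:maxOff) {
      w <- last - off
      ok <- w >= 1 & w <= nw
      ok[ok] <- p[ok] <= starts[w[ok]] + windowBp - 1
      if (!any(ok)) next
      wi <- w[ok]
      agg <- rowsum(cbind(1, v$idxLow[ok], v$idxHigh[ok], v$delta[ok],
                          nlp[ok], up95[ok], dn95[ok], up99[ok], dn99[ok],
                          v$zeroInLow[ok], v$zeroInHigh[ok]), wi)
      idx <- as.integer(rownames(agg))
      df$n_variants[idx] <- df$n_variants[idx] + as.integer(agg[, 1])
      df$mean_idx_low[idx] <- ifelse(is.na(df$mean_idx_low[idx]), 0,
                                     df$mean_idx_low[idx]) + agg[, 2]
      df$mean_idx_high[idx] <- ifelse(is.na(df$mean_idx_high[idx]), 0,
                                      df$mean_idx_high[idx]) + agg[, 3]
      df$mean_delta[idx] <- ifelse(is.na(df$mean_delta[idx]), 0,
                                   df$mean_delta[idx]) + agg[, 4]
      df$mean_neglog10p[idx] <- ifelse(is.na(df$mean_neglog10p[idx]), 0,
                                       df$mean_neglog10p[idx]) + agg[, 5]
      df$count95_up[idx] <- df$count95_up[idx] + as.integer(agg[, 6])
      df$count95_down[idx] <- df$count95_down[idx] + as.integer(agg[, 7])
      df$count99_up[idx] <- df$count99_up[idx] + as.integer(agg[, 8])
      df$count99_down[idx] <- df$count99_down[idx] + as.integer(agg[, 9])
      df$zeros_low[idx] <- df$zeros_low[idx] + as.integer(agg[, 10])
      df$zeros_high[idx] <- df$zeros_high[idx] + as.integer(agg[, 11])
    }
    nz <- df$n_variants > 0
    df$mean_idx_low[nz] <- df$mean_idx_low[nz] / df$n_variants[nz]
    df$mean_idx_high[nz] <- df$mean_idx_high[nz] / df$n_variants[nz]
    df$mean_delta[nz] <- df$mean_delta[nz] / df$n_variants[nz]
    df$mean_neglog10p[nz] <- df$mean_neglog10p[nz] / df$n_variants[nz]
    df
  })
  do.call(rbind, out)
}

#' Write window statistics as TSV
#'
#' @param windows \code{data.frame} from \code{\link{slidingWindowScan}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeWindowTsv <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
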