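#' Directional QTL-variant-count criterion
#'
#' A window qualifies for direction d when its directional QTL-variant count
#' exceeds \code{countThreshold} while the opposite-direction count does not
#' (so no window of a reported run shows opposite-direction excess, and a
#' bidirectional window splits runs). Reported intervals are maximal runs of
#' consecutive qualifying windows spanning at least \code{minSpanBp} from the
#' first window start to the last window end. With \code{mode = "lenient"},
#' runs separated by below-threshold gaps are merged as long as at least
#' \code{minFrac} of the merged windows exceed the threshold (and no gap
#' window shows opposite-direction excess).
#'
#' \code{mode = "region"} applies the one-directionality requirement at
#' region scale instead of window scale: candidate intervals are built per
#' direction from above-threshold windows alone (gap-tolerant merge, fraction
#' \code{minFrac}), and an interval is reported unless an opposite-direction
#' candidate interval overlaps it. In an autopolyploid cross, progeny
#' selected for one donor homolog are depleted of its sister homologs, so
#' isolated opposite-direction windows are expected right at a strong QTL;
#' window-scale vetoes can then mask exactly the windows carrying the signal,
#' which is what this mode avoids.
#'
#' @param windows \code{data.frame} from \code{\link{slidingWindowScan}}.
#' @param countThreshold count that must be exceeded (default 20).
#' @param minSpanBp minimum interval span in bp (default 2e6).
#' @param level which confidence counts feed the rule: \code{"95"} (default)
#'   or \code{"99"}.
#' @param mode \code{"strict"} (every window exceeds), \code{"lenient"}, or
#'   \code{"region"}.
#' @param minFrac minimum fraction of above-threshold windows in lenient
#'   mode (default 0.8).
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{direction} (\code{"up"}/\code{"down"}),
#'   \code{n_windows}.
#' @export
callCountCriterion <- function(windows, countThreshold = 20,
                               minSpanBp = 2e6, level = c("95", "99"),
                               mode = c("strict", "lenient", "region"),
                               minFrac = 0.8) {
  level <- match.arg(level)
  mode <- match.arg(mode)
  upCol <- paste0("count", level, "_up")
  dnCol <- paste0("count", level, "_down")
  out <- list()
  for (cn in unique(windows$chrom)) {
    wc <- windows[windows$chrom == cn, , drop = FALSE]
    wc <- wc[order(wc$start), , drop = FALSE]
    cand <- list(up = NULL, down = NULL)
    for (dir in c("up", "down")) {
      opp <- wc[[if (dir == "up") dnCol else upCol]] > countThreshold
      raw <- wc[[if (dir == "up") upCol else dnCol]] > countThreshold
      hit <- if (mode == "region") raw else raw & !opp
      gapVeto <- if (mode == "region") rep(FALSE, length(opp)) else opp
      runs <- .runsOf(hit)
      if (mode != "strict" && nrow(runs) > 1)
        runs <- .mergeRuns(runs, hit, gapVeto, minFrac)
      for (r in seq_len(nrow(runs))) {
        i1 <- runs$from[r]; i2 <- runs$to[r]
        if (mode != "region" && any(opp[i1:i2])) next
        span <- wc$end[i2] - wc$start[i1] + 1
        if (span < minSpanBp) next
        cand[[dir]] <- rbind(cand[[dir]], data.frame(
          chrom = cn, start = wc$start[i1], end = wc$end[i2],
          direction = dir, n_windows = i2 - i1 + 1L,
          stringsAsFactors = FALSE))
      }
    }
    for (dir in c("up", "down")) {
      cc <- cand[[dir]]
      if (is.null(cc)) next
      if (mode == "region" && !is.null(cand[[setdiff(c("up", "down"), dir)]])) {
        oc <- cand[[setdiff(c("up", "down"), dir)]]
        keep <- vapply(seq_len(nrow(cc)), function(i)
          !any(oc$start <= cc$end[i] & oc$end >= cc$start[i]), logical(1))
        cc <- cc[keep, , drop = FALSE]
      }
      if (nrow(cc)) out[[length(out) + 1L]] <- cc
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      n_windows = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

.runsOf <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(from = starts[r$values], to = ends[r$values])
}

## Greedy left-to-right merge of TRUE-runs across gaps, keeping the
## above-threshold fraction of the merged stretch >= minFrac and refusing
## gaps that contain opposite-direction excess.
.mergeRuns <- function(runs, hit, opp, minFrac) {
  merged <- runs[1, , drop = FALSE]
  for (r in seq_len(nrow(runs))[-1]) {
    i1 <- merged$from[nrow(merged)]
    i2 <- runs$to[r]
    gap <- (merged$to[nrow(merged)] + 1L):(runs$from[r] - 1L)
    frac <- sum(hit[i1:i2]) / (i2 - i1 + 1L)
    if (!any(opp[gap]) && frac >= minFrac) {
      merged$to[nrow(merged)] <- i2
    } else {
      merged <- rbind(merged, runs[r, , drop = FALSE])
    }
  }
  merged
}

#' Zero-index cluster criterion
#'
#' Finds, per chromosome and per bulk, stretches of windows in which
#' zero-SNP-index variants cluster in that bulk but not in the other: a
#' window qualifies when its zero count is at least \code{zeroMin} and at
#' least \code{dominanceRatio} times the other bulk's count. Because
#' window-level zero counts are Poisson-noisy, runs of qualifying windows
#' separated by short gaps are merged as long as at least \code{minFrac} of
#' the merged stretch qualifies (and no gap window qualifies for the other
#' bulk); reported stretches must span at least \code{minSpanBp}.
#'
#' @inheritParams callCountCriterion
#' @param zeroMin minimum zero-index variants per window (default 10).
#' @param dominanceRatio required fold excess over the other bulk (default 5).
#' @param minFrac minimum fraction of qualifying windows in a merged stretch
#'   (default 0.8; 1 forbids gaps).
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{bulk} (\code{"low"}/\code{"high"}), \code{n_windows}.
#' @export
callZeroClusterCriterion <- function(windows, zeroMin = 10,
                                     dominanceRatio = 5, minSpanBp = 2e6,
                                     minFrac = 0.8) {
  out <- list()
  for (cn in unique(windows$chrom)) {
    wc <- windows[windows$chrom == cn, , drop = FALSE]
    wc <- wc[order(wc$start), , drop = FALSE]
    for (bulk in c("low", "high")) {
      zb <- wc[[paste0("zeros_", bulk)]]
      zo <- wc[[paste0("zeros_", if (bulk == "low") "high" else "low")]]
      hit <- zb >= zeroMin & zb >= dominanceRatio * zo
      opp <- zo >= zeroMin & zo >= dominanceRatio * zb
      runs <- .runsOf(hit)
      if (nrow(runs) > 1)
        runs <- .mergeRuns(runs, hit, opp, minFrac)
      for (r in seq_len(nrow(runs))) {
        i1 <- runs$from[r]; i2 <- runs$to[r]
        span <- wc$end[i2] - wc$start[i1] + 1
        if (span < minSpanBp) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = wc$start[i1], end = wc$end[i2],
          bulk = bulk, n_windows = i2 - i1 + 1L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), bulk = character(0),
                      n_windows = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Call candidate QTL regions from the two criteria
#'
#' A region is called wherever a directional count interval (criterion 1)
#' overlaps a zero-cluster interval (criterion 2) on the same chromosome with
#' consistent polarity: an \emph{up} (trait-increasing donor allele) interval
#' must meet a zero cluster in the \emph{low} bulk, and a \emph{down} interval
#' a cluster in the \emph{high} bulk — the bulk depleted of the donor allele
#' sits on the opposite side of the trait effect. Region bounds are the
#' interval intersection; the peak window is the member window with maximal
#' \code{|mean_delta|}.
#'
#' @param countIntervals output of \code{\link{callCountCriterion}}.
#' @param zeroIntervals output of \code{\link{callZeroClusterCriterion}}.
#' @param windows the window table both criteria were evaluated on.
#' @return \code{data.frame} with columns \code{chrom}, \code{start},
#'   \code{end}, \code{direction}, \code{zero_cluster_bulk},
#'   \code{criterion1_met}, \code{criterion2_met}, \code{peak_window_start},
#'   \code{n_support_windows}.
#' @export
callQtlRegions <- function(countIntervals, zeroIntervals, windows) {
  out <- list()
  for (i in seq_len(nrow(countIntervals))) {
    ci <- countIntervals[i, ]
    wantBulk <- if (ci$direction == "up") "low" else "high"
    zz <- zeroIntervals[zeroIntervals$chrom == ci$chrom &
                          zeroIntervals$bulk == wantBulk, , drop = FALSE]
    for (j in seq_len(nrow(zz))) {
      s <- max(ci$start, zz$start[j])
      e <- min(ci$end, zz$end[j])
      if (s > e) next
      wm <- windows[windows$chrom == ci$chrom & windows$start <= e &
                      windows$end >= s & windows$n_variants > 0, , drop = FALSE]
      peak <- if (nrow(wm)) wm$start[which.max(abs(wm$mean_delta))] else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = ci$chrom, start = s, end = e, direction = ci$direction,
        zero_cluster_bulk = wantBulk,
        criterion1_met = TRUE, criterion2_met = TRUE,
        peak_window_start = peak,
        n_support_windows = sum(windows$chrom == ci$chrom &
                                  windows$start <= e & windows$end >= s),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), direction = character(0),
                      zero_cluster_bulk = character(0),
                      criterion1_met = logical(0), criterion2_met = logical(0),
                      peak_window_start = numeric(0),
                      n_support_windows = integer(0), stringsAsFactors = FALSE))
  reg <- do.call(rbind, out)
  .mergeRegions(reg, windows)
}

## union of overlapping called regions of the same chromosome and polarity
.mergeRegions <- function(reg, windows) {
  key <- paste(reg$chrom, reg$direction)
  merged <- list()
  for (k in unique(key)) {
    rr <- reg[key == k, , drop = FALSE]
    rr <- rr[order(rr$start), , drop = FALSE]
    cur <- rr[1, , drop = FALSE]
    for (i in seq_len(nrow(rr))[-1]) {
      if (rr$start[i] <= cur$end + 1) {
        cur$end <- max(cur$end, rr$end[i])
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- rr[i, , drop = FALSE]
      }
    }
    merged[[length(merged) + 1L]] <- cur
  }
  reg <- do.call(rbind, merged)
  for (i in seq_len(nrow(reg))) {
    wm <- windows[windows$chrom == reg$chrom[i] &
                    windows$start <= reg$end[i] & windows$end >= reg$start[i], ,
                  drop = FALSE]
    reg$n_support_windows[i] <- nrow(wm)
    wm <- wm[wm$n_variants > 0, , drop = FALSE]
    reg$peak_window_start[i] <-
      if (nrow(wm)) wm$start[which.max(abs(wm$mean_delta))] else NA_real_
  }
  rownames(reg) <- NULL
  reg
}

#' Nominate allele-specific marker SNPs inside a called region
#'
#' Marker-suitable sites have one bulk SNP-index at (or within
#' \code{zeroTol} of) 0 and the other within \code{simplexTol} of the
#' expected donor index \code{plexity / ploidy} (0.167 for a hexaploid
#' simplex), with polarity consistent with the region direction (an up region
#' requires the near-zero bulk to be the low bulk). Candidates are ranked by
#' total bulk depth (descending), then by \code{|delta|} (descending).
#'
#' @param x scored \code{\linkS4class{BsaVariantSet}}.
#' @param region one row of \code{\link{callQtlRegions}} output.
#' @param zeroTol tolerance on the near-zero bulk index (default 0.02).
#' @param simplexTol tolerance around the expected index (default 0.05).
#' @param topK maximum number of candidates (default 10).
#' @param ploidy parent ploidy (default 6).
#' @return \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{idx_low}, \code{idx_high}, \code{delta},
#'   \code{rank}.
#' @export
selectMarkerCandidates <- function(x, region, zeroTol = 0.02,
                                   simplexTol = 0.05, topK = 10, ploidy = 6) {
  rd <- SummarizedExperiment::rowData(x)
  chrom <- as.character(GenomeInfoDb::seqnames(x))
  pos <- GenomicRanges::start(x)
  inside <- chrom == region$chrom & pos >= region$start & pos <= region$end
  if (!any(inside))
    return(.emptyMarkers())
  rd <- rd[inside, , drop = FALSE]
  pos <- pos[inside]
  chrom <- chrom[inside]
  tdBulk <- totalDepth(x)[inside, c("BULK_LOW", "BULK_HIGH"), drop = FALSE]
  expected <- rd$plexity / ploidy
  lowIsZero <- region$direction == "up"
  zeroIdx <- if (lowIsZero) rd$idxLow else rd$idxHigh
  fullIdx <- if (lowIsZero) rd$idxHigh else rd$idxLow
  keep <- zeroIdx <= zeroTol & abs(fullIdx - expected) <= simplexTol
  if (!any(keep))
    return(.emptyMarkers())
  depth <- rowSums(tdBulk)[keep]
  cand <- data.frame(chrom = chrom[keep], pos = pos[keep],
                     ref = rd$ref[keep], alt = rd$alt[keep],
                     idx_low = rd$idxLow[keep], idx_high = rd$idxHigh[keep],
                     delta = rd$delta[keep], stringsAsFactors = FALSE)
  o <- order(-depth, -abs(cand$delta))
  cand <- cand[o, , drop = FALSE][seq_len(min(topK, nrow(cand))), , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  cand
}

.emptyMarkers <- function()
  data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
             alt = character(0), idx_low = numeric(0), idx_high = numeric(0),
             delta = numeric(0), rank = integer(0), stringsAsFactors = FALSE)
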