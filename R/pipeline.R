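#' Default run configuration
#'
#' Returns the full configuration list understood by
#' \code{\link{runPipeline}}, with the standard defaults of the method
#' (minimum depth 50, ploidy 6, plexity 1 with its allele-fraction window,
#' 100-kb windows at 20-kb increments, count threshold 20 over at least 2 Mb,
#' null simulation with 10000 replicates). \code{minMQ}/\code{adjustMQ} are
#' recorded for provenance of the upstream variant caller only; they act at
#' pileup time and are not applied here.
#'
#' @return Named list of configuration keys.
#' @export
defaultRunConfig <- function() {
  list(
    vcf = NULL, chrom_lengths = NULL, outdir = NULL,
    sample_map = list(P1 = "P1", P2 = "P2",
                      BULK_LOW = "BULK_LOW", BULK_HIGH = "BULK_HIGH"),
    multiallelic = "drop",
    min_depth = 50, max_indel_length = 71,
    ploidy = 6, n_plex = 1, donor_index_range = NULL, max_other_alt_reads = 0,
    replicates = 10000, seed = 1, bulk_size_low = 10, bulk_size_high = 21,
    window_bp = 100000, step_bp = 20000,
    count_threshold = 20, min_span_bp = 2000000,
    zero_min = 10, dominance_ratio = 5, confidence_level = "95",
    count_mode = "strict",
    zero_tol = 0.02, simplex_tol = 0.05, top_k = 10,
    plot = FALSE,
    min_mq = 30, adjust_mq = 70)
}

#' Read a YAML run configuration
#'
#' Keys missing from the file take the \code{\link{defaultRunConfig}} values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultRunConfig()
  for (k in names(user)) cfg[[k]] <- user[[k]]
  cfg
}

.checkRunConfig <- function(cfg) {
  for (k in c("vcf", "chrom_lengths", "outdir"))
    if (is.null(cfg[[k]]))
      stop("configuration error: missing key '", k, "'")
  if (is.null(cfg$sample_map) ||
      !all(.bsaRoles %in% names(cfg$sample_map)))
    stop("configuration error: sample_map must name P1, P2, BULK_LOW, BULK_HIGH")
  for (k in c("vcf", "chrom_lengths"))
    if (!file.exists(cfg[[k]]))
      stop("configuration error: file not found: ", cfg[[k]])
  invisible(cfg)
}

#' Run the full polyploid QTL-seq pipeline
#'
#' Executes read, filter, classification in both donor orientations, scoring
#' against the null simulation, the sliding-window scan, two-criterion QTL
#' region calling and marker nomination. Per orientation (\code{P1}/\code{P2}
#' as donor) it writes \code{scored.tsv}, \code{windows.tsv},
#' \code{regions.tsv}, \code{markers.tsv} and \code{run_metadata.json} under
#' \code{outdir/<donor>/}. All randomness derives from \code{cfg$seed}, so
#' repeated runs produce byte-identical outputs.
#'
#' @param config a configuration list (see \code{\link{defaultRunConfig}}) or
#'   path to a YAML file.
#' @param quiet suppress stage-count log messages.
#' @return Invisibly, a list per orientation with elements \code{scored},
#'   \code{windows}, \code{regions}, \code{markers}.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) readRunConfig(config) else {
    full <- defaultRunConfig()
    for (k in names(config)) full[[k]] <- config[[k]]
    full
  }
  .checkRunConfig(cfg)
  log <- function(...) if (!quiet) message(sprintf(...))
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)

  sampleMap <- unlist(cfg$sample_map)[.bsaRoles]
  x <- readBsaVcf(cfg$vcf, sampleMap, multiallelic = cfg$multiallelic)
  log("parsed %d variant records", nrow(x))
  chromLengths <- readChromLengths(cfg$chrom_lengths)
  xf <- filterVariants(x, cfg$min_depth, cfg$max_indel_length)
  log("retained %d variants after depth/indel filters", nrow(xf))

  sets <- classifyAllVariants(xf, ploidy = cfg$ploidy, nPlex = cfg$n_plex,
                              donorIndexRange = cfg$donor_index_range,
                              maxOtherAltReads = cfg$max_other_alt_reads)
  out <- list()
  for (donor in c("P1", "P2")) {
    xs <- sets[[donor]]
    log("[%s donor] classified %d plexity-%d variants", donor, nrow(xs),
        cfg$n_plex)
    scored <- scoreVariants(xs, nLow = cfg$bulk_size_low,
                            nHigh = cfg$bulk_size_high, ploidy = cfg$ploidy,
                            replicates = cfg$replicates, seed = cfg$seed)
    windows <- slidingWindowScan(scored, chromLengths,
                                 windowBp = cfg$window_bp,
                                 stepBp = cfg$step_bp)
    ci <- callCountCriterion(windows, cfg$count_threshold, cfg$min_span_bp,
                             level = as.character(cfg$confidence_level),
                             mode = cfg$count_mode)
    zi <- callZeroClusterCriterion(windows, cfg$zero_min,
                                   cfg$dominance_ratio, cfg$min_span_bp)
    regions <- callQtlRegions(ci, zi, windows)
    log("[%s donor] %d count interval(s), %d zero-cluster interval(s), %d region(s)",
        donor, nrow(ci), nrow(zi), nrow(regions))
    markers <- do.call(rbind, c(list(.emptyMarkers()),
      lapply(seq_len(nrow(regions)), function(i)
        selectMarkerCandidates(scored, regions[i, ], cfg$zero_tol,
                               cfg$simplex_tol, cfg$top_k, cfg$ploidy))))

    d <- file.path(cfg$outdir, donor)
    dir.create(d, showWarnings = FALSE)
    writeScoredTsv(scored, file.path(d, "scored.tsv"))
    writeWindowTsv(windows, file.path(d, "windows.tsv"))
    utils::write.table(regions, file.path(d, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(markers, file.path(d, "markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    meta <- cfg
    meta$orientation <- donor
    meta$package_version <- as.character(utils::packageVersion("polyBSA"))
    jsonlite::write_json(meta, file.path(d, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    if (isTRUE(cfg$plot)) {
      for (cn in unique(as.character(GenomeInfoDb::seqnames(scored))))
        plotChromosome(windows, scored, cn,
                       file.path(d, paste0("plot_", cn, ".png")),
                       countThreshold = cfg$count_threshold)
    }
    out[[donor]] <- list(scored = scored, windows = windows,
                         regions = regions, markers = markers)
  }
  invisible(out)
}

#' Six-panel per-chromosome diagnostic plot
#'
#' Mirrors the standard polyploid QTL-seq figure layout: per-bulk SNP-index
#' dot plots with the window mean line (zero-index variants in a distinct
#' colour), their superimposition, the delta SNP-index with 95\%/99\%
#' threshold bands, the window mean -log10 P, and the directional QTL-variant
#' count (positive delta plotted upward, negative downward, with the count
#' threshold line).
#'
#' @param windows window table from \code{\link{slidingWindowScan}}.
#' @param scored scored \code{\linkS4class{BsaVariantSet}}.
#' @param chrom chromosome to plot.
#' @param outPath output PNG path.
#' @param countThreshold threshold line for the count panel (default 20).
#' @return \code{outPath}, invisibly.
#' @export
plotChromosome <- function(windows, scored, chrom, outPath,
                           countThreshold = 20) {
  rd <- SummarizedExperiment::rowData(scored)
  sel <- as.character(GenomeInfoDb::seqnames(scored)) == chrom
  pos <- GenomicRanges::start(scored)[sel] / 1e6
  v <- rd[sel, , drop = FALSE]
  w <- windows[windows$chrom == chrom, , drop = FALSE]
  wmid <- (w$start + w$end) / 2e6
  xlim <- range(c(0, w$end / 1e6))

  grDevices::png(outPath, width = 1400, height = 1800, res = 150)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(6, 1), mar = c(2.5, 4, 1.5, 1), mgp = c(2, 0.7, 0))

  idxPanel <- function(idx, zero, main, col, wcol, wline) {
    graphics::plot(pos, idx, pch = 16, cex = 0.3, col = col, xlim = xlim,
                   ylim = c(0, max(0.3, if (length(idx)) max(idx) else 0)),
                   xlab = "", ylab = "SNP-index", main = main)
    graphics::points(pos[zero], idx[zero], pch = 16, cex = 0.4,
                     col = "darkgreen")
    graphics::lines(wmid, wline, col = wcol, lwd = 2)
  }
  n <- nrow(v)
  if (n) {
    idxPanel(v$idxLow, v$zeroInLow, paste0(chrom, ": low bulk"),
             "grey50", "blue", w$mean_idx_low)
    idxPanel(v$idxHigh, v$zeroInHigh, "high bulk",
             "grey50", "red", w$mean_idx_high)
    graphics::plot(wmid, w$mean_idx_low, type = "l", col = "blue", lwd = 2,
                   xlim = xlim, ylim = c(0, 0.3), xlab = "", ylab = "SNP-index",
                   main = "superimposed window means")
    graphics::lines(wmid, w$mean_idx_high, col = "red", lwd = 2)
    graphics::plot(pos, v$delta, pch = 16, cex = 0.3, col = "grey50",
                   xlim = xlim, ylim = c(-0.35, 0.35), xlab = "",
                   ylab = "delta SNP-index", main = "delta SNP-index")
    graphics::lines(wmid, w$mean_delta, col = "darkgreen", lwd = 2)
    graphics::lines(pos, v$upper95, col = "orange", lty = 2)
    graphics::lines(pos, v$lower95, col = "orange", lty = 2)
    graphics::lines(pos, v$upper99, col = "red", lty = 2)
    graphics::lines(pos, v$lower99, col = "red", lty = 2)
    graphics::abline(h = 0, col = "grey70")
  } else {
    for (i in 1:4)
      graphics::plot(0, 0, type = "n", xlim = xlim, ylim = c(0, 1),
                     xlab = "", ylab = "", main = if (i == 1)
                       paste0(chrom, ": no variants") else "")
  }
  graphics::plot(wmid, w$mean_neglog10p, type = "l", col = "darkgreen",
                 lwd = 2, xlim = xlim, xlab = "", ylab = "-log10 P",
                 main = "window -log10 P",
                 ylim = c(0, max(1, w$mean_neglog10p, na.rm = TRUE)))
  ymax <- max(countThreshold * 1.5, w$count95_up, w$count95_down)
  graphics::plot(wmid, w$count95_up, type = "h", col = "orange", xlim = xlim,
                 ylim = c(-ymax, ymax), xlab = "position (Mb)",
                 ylab = "QTL variant count", main = "QTL variant count")
  graphics::points(wmid, -w$count95_down, type = "h", col = "orange")
  graphics::points(wmid, w$count99_up, type = "h", col = "red")
  graphics::points(wmid, -w$count99_down, type = "h", col = "red")
  graphics::abline(h = c(countThreshold, -countThreshold), col = "red")
  graphics::abline(h = 0, col = "grey40")
  invisible(outPath)
}
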