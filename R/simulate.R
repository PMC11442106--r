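#' Configuration for a synthetic autopolyploid F1 cross
#'
#' Defines the generative model of the built-in simulator: two parents whose
#' variants are simplex/duplex/triplex in one parent and nulliplex in the
#' other, polysomic inheritance through random bivalent pairing (optionally
#' with Poisson crossovers, Haldane map), an additive QTL phenotype with
#' Gaussian noise, extreme-phenotype bulking, and Poisson/binomial read
#' sampling.
#'
#' @param chromLengths named vector of chromosome lengths in bp.
#' @param ploidy even integer (default 6).
#' @param variantDensity variants per bp (default 1/5000).
#' @param plexityMix proportions of simplex/duplex/triplex variants (summing
#'   to 1) within each donor parent.
#' @param donorMix proportions of variants donated by P1 vs P2.
#' @param nProgeny F1 population size (default 126).
#' @param qtls \code{data.frame} with columns \code{chrom}, \code{pos},
#'   \code{donor} ("P1"/"P2"), \code{effect} (trait units per allele copy)
#'   and optionally \code{plexity} (default 1); NULL for no QTLs.
#' @param phenotypeNoiseSd Gaussian phenotype noise SD in trait units
#'   (default 0).
#' @param bulkLowN,bulkHighN bulk sizes (defaults 10 and 21).
#' @param depthMean mean sequencing depth per sample per site (default 100).
#' @param recombination if TRUE, gametes are recombinant chromatids with
#'   Poisson crossovers; if FALSE (default) whole homologs are transmitted.
#' @param cmPerMb recombination rate used when \code{recombination = TRUE}
#'   (default 3 cM/Mb).
#' @param seed integer seed driving every stochastic step.
#' @return A validated list of class \code{"CrossConfig"}.
#' @export
crossConfig <- function(chromLengths, ploidy = 6, variantDensity = 1 / 5000,
                        plexityMix = c(simplex = 0.6, duplex = 0.25,
                                       triplex = 0.15),
                        donorMix = c(P1 = 0.5, P2 = 0.5),
                        nProgeny = 126, qtls = NULL, phenotypeNoiseSd = 0,
                        bulkLowN = 10, bulkHighN = 21, depthMean = 100,
                        recombination = FALSE, cmPerMb = 3, seed = 1) {
  stopifnot(length(chromLengths) >= 1, !is.null(names(chromLengths)),
            ploidy %% 2 == 0, ploidy >= 4,
            abs(sum(plexityMix) - 1) < 1e-8, abs(sum(donorMix) - 1) < 1e-8,
            nProgeny >= 1, bulkLowN >= 1, bulkHighN >= 1,
            bulkLowN + bulkHighN <= nProgeny, depthMean >= 1)
  if (!is.null(qtls) && nrow(qtls)) {
    stopifnot(all(c("chrom", "pos", "donor", "effect") %in% colnames(qtls)),
              all(qtls$chrom %in% names(chromLengths)),
              all(qtls$pos >= 1),
              all(qtls$pos <= chromLengths[qtls$chrom]),
              all(qtls$donor %in% c("P1", "P2")))
    if (is.null(qtls$plexity)) qtls$plexity <- 1L
  }
  structure(list(chromLengths = chromLengths, ploidy = ploidy,
                 variantDensity = variantDensity, plexityMix = plexityMix,
                 donorMix = donorMix, nProgeny = nProgeny, qtls = qtls,
                 phenotypeNoiseSd = phenotypeNoiseSd, bulkLowN = bulkLowN,
                 bulkHighN = bulkHighN, depthMean = depthMean,
                 recombination = recombination, cmPerMb = cmPerMb,
                 seed = seed),
            class = "CrossConfig")
}

.deriveSeed <- function(seed, k) (as.double(seed) + k * 1000003) %% 2147483647

## top-k indices per column of a ploidy x m uniform matrix = random k-subset
.randomSubsets <- function(ploidy, k, m) {
  r <- matrix(stats::runif(ploidy * m), ploidy, m)
  out <- matrix(0L, k, m)
  tr <- t(r)
  for (i in seq_len(k)) {
    idx <- max.col(tr)
    out[i, ] <- idx
    tr[cbind(seq_len(m), idx)] <- -Inf
  }
  out
}

#' Build a synthetic cross
#'
#' Places variants along each chromosome (Poisson count at the configured
#' density, uniform positions), assigns each a donor parent, plexity and the
#' marked homolog(s), assigns QTLs to donor homologs, and simulates each
#' progeny's meiosis in both parents: without recombination the gamete is a
#' uniform random half of the parent's homologs; with recombination homologs
#' are paired into random bivalents and each transmitted chromatid switches
#' homolog at Poisson crossover points.
#'
#' @param cfg a \code{\link{crossConfig}}.
#' @return An object of class \code{"BsaCross"} (list) holding the variant
#'   table, QTL homolog assignments and per-progeny meiosis outcomes.
#' @export
makeCross <- function(cfg) {
  stopifnot(inherits(cfg, "CrossConfig"))
  set.seed(as.integer(cfg$seed))
  ploidy <- cfg$ploidy
  half <- ploidy / 2
  chroms <- names(cfg$chromLengths)

  vlist <- lapply(chroms, function(cn) {
    len <- cfg$chromLengths[[cn]]
    nv <- stats::rpois(1, len * cfg$variantDensity)
    nv <- min(nv, len)
    if (nv == 0)
      return(data.frame(chrom = character(0), pos = integer(0),
                        donor = character(0), plexity = integer(0)))
    pos <- sort(sample.int(len, nv))
    donor <- names(cfg$donorMix)[
      sample.int(length(cfg$donorMix), nv, TRUE, prob = cfg$donorMix)]
    plexity <- sample.int(3L, nv, TRUE, prob = cfg$plexityMix)
    data.frame(chrom = cn, pos = pos, donor = donor, plexity = plexity,
               stringsAsFactors = FALSE)
  })
  variants <- do.call(rbind, vlist)
  nv <- nrow(variants)
  hom <- matrix(NA_integer_, nv, 3L)
  if (nv) {
    subs <- .randomSubsets(ploidy, 3L, nv)
    for (k in 1:3)
      hom[variants$plexity >= k, k] <- subs[k, variants$plexity >= k]
  }

  qtls <- cfg$qtls
  qtlHom <- NULL
  if (!is.null(qtls) && nrow(qtls)) {
    qs <- .randomSubsets(ploidy, 3L, nrow(qtls))
    qtlHom <- matrix(NA_integer_, nrow(qtls), 3L)
    for (k in 1:3)
      qtlHom[qtls$plexity >= k, k] <- qs[k, qtls$plexity >= k]
  }

  nP <- cfg$nProgeny
  nC <- length(chroms)
  if (!cfg$recombination) {
    inh <- list()
    for (par in c("P1", "P2")) {
      a <- array(FALSE, c(ploidy, nP, nC))
      picks <- .randomSubsets(ploidy, half, nP * nC)
      for (k in seq_len(half)) {
        idx <- cbind(picks[k, ],
                     rep(seq_len(nP), times = nC),
                     rep(seq_len(nC), each = nP))
        a[idx] <- TRUE
      }
      inh[[par]] <- a
    }
    meio <- NULL
  } else {
    inh <- NULL
    meio <- list()
    for (par in c("P1", "P2")) {
      meio[[par]] <- vector("list", nC)
      for (ci in seq_len(nC)) {
        lenM <- cfg$chromLengths[[ci]] * cfg$cmPerMb * 1e-8  # Morgans
        meio[[par]][[ci]] <- lapply(seq_len(nP), function(m) {
          pairing <- matrix(sample.int(ploidy), 2L, half)
          nx <- stats::rpois(half, lenM)
          switches <- lapply(nx, function(k)
            sort(stats::runif(k, 1, cfg$chromLengths[[ci]])))
          list(pairing = pairing,
               start = sample.int(2L, half, TRUE) - 1L,
               switches = switches)
        })
      }
    }
  }
  structure(list(cfg = cfg, variants = variants, hom = hom,
                 qtls = qtls, qtlHom = qtlHom, inh = inh, meio = meio,
                 chroms = chroms),
            class = "BsaCross")
}

## dose of homolog set `homRows` (matrix n x 3, NA padded) of `parent` for the
## given progeny members at positions `pos` on chromosome index `ci`
.dosesOn <- function(cross, parent, ci, pos, homRows, members) {
  n <- length(pos)
  nm <- length(members)
  doses <- matrix(0L, n, nm)
  if (n == 0L || nm == 0L) return(doses)
  if (!cross$cfg$recombination) {
    I <- cross$inh[[parent]][, members, ci, drop = FALSE]
    dim(I) <- c(cross$cfg$ploidy, nm)
    for (k in 1:3) {
      h <- homRows[, k]
      ok <- !is.na(h)
      if (!any(ok)) next
      doses[ok, ] <- doses[ok, ] + I[h[ok], , drop = FALSE]
    }
  } else {
    half <- cross$cfg$ploidy / 2
    for (mi in seq_len(nm)) {
      me <- cross$meio[[parent]][[ci]][[members[mi]]]
      bivOf <- integer(cross$cfg$ploidy)
      for (b in seq_len(half)) bivOf[me$pairing[, b]] <- b
      for (k in 1:3) {
        h <- homRows[, k]
        ok <- which(!is.na(h))
        if (!length(ok)) next
        bv <- bivOf[h[ok]]
        for (b in unique(bv)) {
          ii <- ok[bv == b]
          parity <- (me$start[b] +
                       findInterval(pos[ii], me$switches[[b]])) %% 2L
          active <- me$pairing[cbind(parity + 1L, rep(b, length(ii)))]
          doses[ii, mi] <- doses[ii, mi] + (active == h[ii])
        }
      }
    }
  }
  doses
}

#' Per-progeny allele doses of simulated variants
#'
#' @param cross a \code{\link{makeCross}} result.
#' @param rows integer indices of variants (default all).
#' @param members progeny indices (default all).
#' @return Integer matrix, variants x progeny.
#' @export
progenyDoses <- function(cross, rows = seq_len(nrow(cross$variants)),
                         members = seq_len(cross$cfg$nProgeny)) {
  v <- cross$variants[rows, , drop = FALSE]
  hom <- cross$hom[rows, , drop = FALSE]
  doses <- matrix(0L, nrow(v), length(members))
  for (ci in seq_along(cross$chroms)) {
    for (par in c("P1", "P2")) {
      sel <- which(v$chrom == cross$chroms[ci] & v$donor == par)
      if (!length(sel)) next
      doses[sel, ] <- .dosesOn(cross, par, ci, v$pos[sel],
                               hom[sel, , drop = FALSE], members)
    }
  }
  doses
}

.qtlDoses <- function(cross, members = seq_len(cross$cfg$nProgeny)) {
  q <- cross$qtls
  if (is.null(q) || !nrow(q))
    return(matrix(0L, 0, length(members)))
  doses <- matrix(0L, nrow(q), length(members))
  for (i in seq_len(nrow(q))) {
    ci <- match(q$chrom[i], cross$chroms)
    doses[i, ] <- .dosesOn(cross, q$donor[i], ci, q$pos[i],
                           cross$qtlHom[i, , drop = FALSE], members)
  }
  doses
}

#' Additive QTL phenotypes
#'
#' \code{phenotype = sum(QTL dose * effect) + N(0, phenotypeNoiseSd)}, one
#' value per progeny, reproducible from the cross seed.
#'
#' @param cross a \code{\link{makeCross}} result.
#' @return Numeric vector of length \code{nProgeny}.
#' @export
assignPhenotypes <- function(cross) {
  cfg <- cross$cfg
  set.seed(.deriveSeed(cfg$seed, 1))
  phen <- rep(0, cfg$nProgeny)
  if (!is.null(cfg$qtls) && nrow(cfg$qtls)) {
    qd <- .qtlDoses(cross)
    phen <- as.vector(crossprod(qd, cfg$qtls$effect))
  }
  phen + stats::rnorm(cfg$nProgeny, 0, cfg$phenotypeNoiseSd)
}

#' Select extreme-phenotype bulks
#'
#' Takes the lowest \code{bulkLowN} and highest \code{bulkHighN} phenotype
#' ranks, reading both from the two ends of one stable ordering (ties broken
#' by progeny index), so the selection is deterministic and the bulks are
#' always disjoint even under completely tied phenotypes.
#'
#' @param phenotypes numeric vector, one per progeny.
#' @param bulkLowN,bulkHighN bulk sizes.
#' @return List with integer vectors \code{low} and \code{high}.
#' @export
makeBulks <- function(phenotypes, bulkLowN, bulkHighN) {
  n <- length(phenotypes)
  stopifnot(bulkLowN + bulkHighN <= n)
  o <- order(phenotypes, seq_len(n))
  list(low = sort(o[seq_len(bulkLowN)]),
       high = sort(o[seq.int(n - bulkHighN + 1L, n)]))
}

#' Sample sequencing read counts for the four roles
#'
#' Total depth per sample per site is Poisson(\code{depthMean}) floored at 1.
#' Parental alternate reads are binomial at the true parental allele fraction
#' (\code{plexity/ploidy} for the donor, 0 for the nulliplex parent); bulk
#' alternate reads are binomial at the bulk allele frequency (member dose sum
#' over \code{ploidy * n} homologs).
#'
#' @param cross a \code{\link{makeCross}} result.
#' @param bulks a \code{\link{makeBulks}} result.
#' @return List with matrices \code{refDepth}, \code{altDepth} (variants x 4
#'   roles) and numeric vectors \code{freqLow}, \code{freqHigh} of true bulk
#'   allele frequencies.
#' @export
sampleReadCounts <- function(cross, bulks) {
  cfg <- cross$cfg
  set.seed(.deriveSeed(cfg$seed, 2))
  v <- cross$variants
  nv <- nrow(v)
  dep <- matrix(pmax(1L, stats::rpois(nv * 4L, cfg$depthMean)), nv, 4L,
                dimnames = list(NULL, .bsaRoles))
  alt <- matrix(0L, nv, 4L, dimnames = list(NULL, .bsaRoles))
  if (nv) {
    parentFrac <- v$plexity / cfg$ploidy
    isP1 <- v$donor == "P1"
    alt[isP1, "P1"] <- stats::rbinom(sum(isP1), dep[isP1, "P1"],
                                     parentFrac[isP1])
    alt[!isP1, "P2"] <- stats::rbinom(sum(!isP1), dep[!isP1, "P2"],
                                      parentFrac[!isP1])
    sLow <- rowSums(progenyDoses(cross, members = bulks$low))
    sHigh <- rowSums(progenyDoses(cross, members = bulks$high))
    freqLow <- sLow / (cfg$ploidy * length(bulks$low))
    freqHigh <- sHigh / (cfg$ploidy * length(bulks$high))
    alt[, "BULK_LOW"] <- stats::rbinom(nv, dep[, "BULK_LOW"], freqLow)
    alt[, "BULK_HIGH"] <- stats::rbinom(nv, dep[, "BULK_HIGH"], freqHigh)
  } else {
    freqLow <- freqHigh <- numeric(0)
  }
  list(refDepth = dep - alt, altDepth = alt,
       freqLow = freqLow, freqHigh = freqHigh)
}

.randomAlleles <- function(nv) {
  bases <- c("A", "C", "G", "T")
  ref <- bases[sample.int(4L, nv, TRUE)]
  alt <- bases[(match(ref, bases) + sample.int(3L, nv, TRUE) - 1L) %% 4L + 1L]
  list(ref = ref, alt = alt)
}

#' Run the whole simulator
#'
#' Convenience wrapper: \code{\link{makeCross}}, \code{\link{assignPhenotypes}},
#' \code{\link{makeBulks}}, \code{\link{sampleReadCounts}}, assembly into a
#' \code{\linkS4class{BsaVariantSet}} and a truth table.
#'
#' @param cfg a \code{\link{crossConfig}}.
#' @return List with elements \code{variantSet}
#'   (\code{\linkS4class{BsaVariantSet}}), \code{truth} (per-variant
#'   \code{data.frame}: donor, plexity, homologs, \code{linked_qtl}),
#'   \code{phenotypes}, \code{bulks}, \code{cross}, \code{counts}.
#' @export
simulateBsaCross <- function(cfg) {
  cross <- makeCross(cfg)
  phen <- assignPhenotypes(cross)
  bulks <- makeBulks(phen, cfg$bulkLowN, cfg$bulkHighN)
  counts <- sampleReadCounts(cross, bulks)
  v <- cross$variants
  nv <- nrow(v)
  set.seed(.deriveSeed(cfg$seed, 3))
  al <- .randomAlleles(nv)
  gr <- GenomicRanges::GRanges(
    v$chrom, IRanges::IRanges(v$pos, width = 1L),
    ref = al$ref, alt = al$alt,
    seqlengths = stats::setNames(as.integer(cfg$chromLengths),
                                 names(cfg$chromLengths)))
  vs <- BsaVariantSet(gr, counts$refDepth, counts$altDepth)
  linked <- rep(FALSE, nv)
  if (!is.null(cross$qtls) && nrow(cross$qtls)) {
    for (i in seq_len(nrow(cross$qtls))) {
      qh <- stats::na.omit(cross$qtlHom[i, ])
      share <- v$chrom == cross$qtls$chrom[i] &
        v$donor == cross$qtls$donor[i] &
        (cross$hom[, 1] %in% qh |
           (!is.na(cross$hom[, 2]) & cross$hom[, 2] %in% qh) |
           (!is.na(cross$hom[, 3]) & cross$hom[, 3] %in% qh))
      linked <- linked | share
    }
  }
  truth <- data.frame(chrom = v$chrom, pos = v$pos, donor = v$donor,
                      plexity = v$plexity,
                      hom1 = cross$hom[, 1], hom2 = cross$hom[, 2],
                      hom3 = cross$hom[, 3], linked_qtl = linked,
                      freq_low = counts$freqLow, freq_high = counts$freqHigh,
                      stringsAsFactors = FALSE)
  list(variantSet = vs, truth = truth, phenotypes = phen, bulks = bulks,
       cross = cross, counts = counts)
}

#' Write the simulated cross as VCF plus truth tables
#'
#' Emits a minimal valid VCF v4.2 with four samples (\code{P1}, \code{P2},
#' \code{BULK_LOW}, \code{BULK_HIGH}) carrying \code{AD} genotype fields, a
#' per-variant truth TSV, a per-progeny phenotype TSV (with bulk membership),
#' and a chromosome-length TSV.
#'
#' @param sim a \code{\link{simulateBsaCross}} result.
#' @param vcfPath,truthPath,progenyPath,chromLengthsPath output paths
#'   (any of the last three may be NULL to skip).
#' @return \code{vcfPath}, invisibly.
#' @export
writeCrossVcf <- function(sim, vcfPath, truthPath = NULL, progenyPath = NULL,
                          chromLengthsPath = NULL) {
  cfg <- sim$cross$cfg
  vs <- sim$variantSet
  rd <- SummarizedExperiment::rowData(vs)
  refd <- refDepth(vs); altd <- altDepth(vs)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=polyBSA-simulator",
           sprintf("##contig=<ID=%s,length=%d>", names(cfg$chromLengths),
                   as.integer(cfg$chromLengths)),
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths (ref,alt)\">"),
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", .bsaRoles), collapse = "\t"))
  n <- nrow(vs)
  if (n) {
    samp <- matrix(vapply(seq_len(4L), function(j)
      paste0(refd[, j], ",", altd[, j]), character(n)), n, 4L)
    body <- paste(as.character(GenomeInfoDb::seqnames(vs)),
                  GenomicRanges::start(vs), ".", rd$ref, rd$alt, ".", "PASS",
                  ".", "AD", samp[, 1], samp[, 2], samp[, 3], samp[, 4],
                  sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), vcfPath)
  if (!is.null(truthPath))
    utils::write.table(sim$truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(progenyPath)) {
    prog <- data.frame(progeny = seq_along(sim$phenotypes),
                       phenotype = sim$phenotypes,
                       bulk = ifelse(seq_along(sim$phenotypes) %in%
                                       sim$bulks$low, "low",
                                     ifelse(seq_along(sim$phenotypes) %in%
                                              sim$bulks$high, "high", "none")))
    utils::write.table(prog, progenyPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(chromLengthsPath))
    utils::write.table(
      data.frame(names(cfg$chromLengths), as.integer(cfg$chromLengths)),
      chromLengthsPath, sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  invisible(vcfPath)
}
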