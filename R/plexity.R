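#' Allele-read fraction (SNP-index)
#'
#' The fraction of reads at a site carrying the alternate (donor) allele:
#' \code{alt / (ref + alt)}, kept at full precision. This single definition
#' serves both as the parental allele fraction used for plexity classification
#' and as the per-bulk SNP-index.
#'
#' @param refDepth,altDepth non-negative read counts (vectorised).
#' @return Numeric vector of fractions in [0, 1].
#' @examples
#' snpIndex(118, 89)   # 0.4299..., prints as 0.43
#' snpIndex(172, 0)    # 0
#' @export
snpIndex <- function(refDepth, altDepth) {
  tot <- refDepth + altDepth
  if (any(tot < 1))
    stop("undefined allele fraction: zero total depth")
  altDepth / tot
}

#' @rdname snpIndex
#' @export
alleleFraction <- snpIndex

#' Default donor-parent allele-fraction range per plexity
#'
#' For a hexaploid, a parent carrying the allele on 1, 2 or 3 of its 6
#' homologs has expected allele fraction 1/6, 2/6 or 3/6; the acceptance
#' windows around those expectations are [0.08, 0.25], [0.22, 0.45] and
#' [0.38, 0.62] for plexity 1, 2 and 3.
#'
#' @param nPlex target plexity, 1 (simplex), 2 (duplex) or 3 (triplex).
#' @return Length-2 numeric vector (lower, upper), closed interval.
#' @export
plexityRange <- function(nPlex) {
  switch(as.character(nPlex),
         "1" = c(0.08, 0.25),
         "2" = c(0.22, 0.45),
         "3" = c(0.38, 0.62),
         stop("nPlex must be 1, 2 or 3"))
}

#' Classify variants by donor parent and plexity
#'
#' A variant is accepted for donor parent \code{donor} at plexity \code{nPlex}
#' when (i) the donor parent's allele-read fraction lies inside
#' \code{donorIndexRange} (closed interval) and (ii) the other parent is
#' nulliplex, operationalised as at most \code{maxOtherAltReads} alternate
#' reads. Rejected variants carry a reason code
#' (\code{fraction_out_of_range} or \code{other_parent_not_nulliplex}).
#'
#' @param x a filtered \code{\linkS4class{BsaVariantSet}}.
#' @param donor \code{"P1"} or \code{"P2"}: the parent assumed to carry the
#'   allele.
#' @param ploidy even integer >= 4 (default 6).
#' @param nPlex target plexity (default 1, simplex).
#' @param donorIndexRange optional override of \code{plexityRange(nPlex)}.
#' @param maxOtherAltReads maximum alternate reads tolerated in the nulliplex
#'   parent (default 0).
#' @param keepRejected if TRUE, return all variants with an extra
#'   \code{rejectReason} column (\code{NA} for accepted) instead of
#'   subsetting.
#' @return A \code{BsaVariantSet} of accepted variants with \code{rowData}
#'   columns \code{donor}, \code{plexity}, \code{donorFraction} (or, with
#'   \code{keepRejected = TRUE}, all variants plus \code{rejectReason}).
#' @export
classifyVariants <- function(x, donor = c("P1", "P2"), ploidy = 6, nPlex = 1,
                             donorIndexRange = NULL, maxOtherAltReads = 0,
                             keepRejected = FALSE) {
  donor <- match.arg(donor)
  stopifnot(ploidy %% 2 == 0, ploidy >= 4)
  if (is.null(donorIndexRange)) donorIndexRange <- plexityRange(nPlex)
  stopifnot(length(donorIndexRange) == 2,
            donorIndexRange[1] >= 0, donorIndexRange[1] < donorIndexRange[2],
            donorIndexRange[2] <= 1)
  other <- if (donor == "P1") "P2" else "P1"
  if (nrow(x) == 0L) {
    rd <- SummarizedExperiment::rowData(x)
    rd$donor <- character(0); rd$plexity <- integer(0)
    rd$donorFraction <- numeric(0)
    if (keepRejected) rd$rejectReason <- character(0)
    SummarizedExperiment::rowData(x) <- rd
    return(x)
  }
  frac <- unname(altDepth(x)[, donor] / pmax(totalDepth(x)[, donor], 1L))
  inRange <- frac >= donorIndexRange[1] & frac <= donorIndexRange[2]
  nulliplex <- altDepth(x)[, other] <= maxOtherAltReads
  reason <- rep(NA_character_, nrow(x))
  reason[!inRange] <- "fraction_out_of_range"
  reason[inRange & !nulliplex] <- "other_parent_not_nulliplex"
  rd <- SummarizedExperiment::rowData(x)
  rd$donor <- donor
  rd$plexity <- as.integer(nPlex)
  rd$donorFraction <- frac
  if (keepRejected) {
    rd$rejectReason <- reason
    SummarizedExperiment::rowData(x) <- rd
    return(x)
  }
  SummarizedExperiment::rowData(x) <- rd
  x[inRange & nulliplex, ]
}

#' Classify in both donor orientations
#'
#' Runs \code{\link{classifyVariants}} with each parent as donor and returns
#' two disjoint sets. A site accepted in both orientations is ambiguous about
#' its segregating source and is discarded from both.
#'
#' @inheritParams classifyVariants
#' @return Named list with elements \code{P1} and \code{P2}, each a classified
#'   \code{BsaVariantSet}.
#' @export
classifyAllVariants <- function(x, ploidy = 6, nPlex = 1,
                                donorIndexRange = NULL, maxOtherAltReads = 0) {
  a1 <- classifyVariants(x, "P1", ploidy, nPlex, donorIndexRange,
                         maxOtherAltReads, keepRejected = TRUE)
  a2 <- classifyVariants(x, "P2", ploidy, nPlex, donorIndexRange,
                         maxOtherAltReads, keepRejected = TRUE)
  ok1 <- is.na(SummarizedExperiment::rowData(a1)$rejectReason)
  ok2 <- is.na(SummarizedExperiment::rowData(a2)$rejectReason)
  both <- ok1 & ok2
  sel1 <- ok1 & !both
  sel2 <- ok2 & !both
  out1 <- a1[sel1, ]
  out2 <- a2[sel2, ]
  rd1 <- SummarizedExperiment::rowData(out1); rd1$rejectReason <- NULL
  rd2 <- SummarizedExperiment::rowData(out2); rd2$rejectReason <- NULL
  SummarizedExperiment::rowData(out1) <- rd1
  SummarizedExperiment::rowData(out2) <- rd2
  list(P1 = out1, P2 = out2)
}
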