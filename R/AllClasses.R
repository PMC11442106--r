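#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @import methods
NULL

## Sample roles, in fixed column order.
.bsaRoles <- c("P1", "P2", "BULK_LOW", "BULK_HIGH")

#' Container for multi-sample variant read depths
#'
#' \code{BsaVariantSet} extends \code{RangedSummarizedExperiment}. Rows are
#' biallelic variant sites, columns are the four sample roles of a bulked
#' segregant design (\code{P1}, \code{P2}, \code{BULK_LOW}, \code{BULK_HIGH}),
#' and the two assays \code{refDepth} and \code{altDepth} hold reference- and
#' alternate-allele read counts. \code{rowRanges} carries the site coordinates
#' (1-based, width 1 anchored at the VCF POS) with \code{ref} and \code{alt}
#' allele strings in its metadata columns. Classification
#' (\code{\link{classifyVariants}}) and scoring (\code{\link{scoreVariants}})
#' append further \code{rowData} columns.
#'
#' @slot .. see \code{RangedSummarizedExperiment}; no additional slots.
#' @aliases BsaVariantSet-class
#' @exportClass BsaVariantSet
setClass("BsaVariantSet", contains = "RangedSummarizedExperiment")

setValidity("BsaVariantSet", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("refDepth", "altDepth") %in% an))
    msg <- c(msg, "assays must include 'refDepth' and 'altDepth'")
  if (!identical(colnames(object), .bsaRoles))
    msg <- c(msg, sprintf("colnames must be %s in that order",
                          paste(.bsaRoles, collapse = ", ")))
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("ref", "alt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'ref' and 'alt' allele columns")
  if (all(c("refDepth", "altDepth") %in% an)) {
    dp <- SummarizedExperiment::assay(object, "refDepth")
    da <- SummarizedExperiment::assay(object, "altDepth")
    if (length(dp) && (min(dp) < 0 || min(da) < 0))
      msg <- c(msg, "depths must be non-negative")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a BsaVariantSet
#'
#' @param rowRanges \code{GRanges} of variant positions (width-1 ranges at the
#'   VCF POS) with metadata columns \code{ref} and \code{alt}.
#' @param refDepth,altDepth integer matrices, one row per variant, columns
#'   \code{P1}, \code{P2}, \code{BULK_LOW}, \code{BULK_HIGH}.
#' @return A \code{\linkS4class{BsaVariantSet}}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 200), width = 1),
#'                              ref = c("A", "C"), alt = c("T", "G"))
#' dp <- matrix(100L, 2, 4, dimnames = list(NULL, c("P1","P2","BULK_LOW","BULK_HIGH")))
#' BsaVariantSet(gr, refDepth = dp, altDepth = dp)
#' @export
BsaVariantSet <- function(rowRanges, refDepth, altDepth) {
  storage.mode(refDepth) <- "integer"
  storage.mode(altDepth) <- "integer"
  colnames(refDepth) <- .bsaRoles
  colnames(altDepth) <- .bsaRoles
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(refDepth = refDepth, altDepth = altDepth),
    rowRanges = rowRanges,
    colData = S4Vectors::DataFrame(role = .bsaRoles, row.names = .bsaRoles))
  new("BsaVariantSet", se)
}

#' Null distribution of the delta SNP-index at one read-depth pair
#'
#' Holds the Monte-Carlo sample of the delta SNP-index (high bulk minus low
#' bulk) under the no-QTL hypothesis for a given segregation model, bulk sizes
#' and per-bulk read depths, together with empirical 95\% and 99\% confidence
#' thresholds.
#'
#' @slot nLow,nHigh bulk sizes (individuals).
#' @slot depthLow,depthHigh read depths at which reads were sampled.
#' @slot ploidy,plexity segregation model parameters.
#' @slot replicates Monte-Carlo sample size.
#' @slot deltaSamples numeric vector of simulated delta values.
#' @slot absDeltaSorted sorted \code{abs(deltaSamples)}, cached for P-value
#'   lookups.
#' @slot thresholds 2 x 2 matrix, rows \code{lower}/\code{upper}, columns
#'   \code{"95"}/\code{"99"}.
#' @aliases NullDistribution-class
#' @exportClass NullDistribution
setClass("NullDistribution",
  representation(nLow = "integer", nHigh = "integer",
                 depthLow = "integer", depthHigh = "integer",
                 ploidy = "integer", plexity = "integer",
                 replicates = "integer",
                 deltaSamples = "numeric", absDeltaSorted = "numeric",
                 thresholds = "matrix"))

setValidity("NullDistribution", function(object) {
  msg <- NULL
  th <- object@thresholds
  if (!identical(dim(th), c(2L, 2L)))
    msg <- c(msg, "thresholds must be a 2 x 2 matrix")
  else {
    if (th["lower", "99"] > th["lower", "95"] ||
        th["upper", "99"] < th["upper", "95"])
      msg <- c(msg, "99% interval must contain the 95% interval")
  }
  if (length(object@deltaSamples) != object@replicates)
    msg <- c(msg, "deltaSamples length must equal replicates")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution (no-QTL delta SNP-index)\n")
  cat(sprintf("  ploidy %d, plexity %d; bulks n=%d/%d; depths %d/%d; %d replicates\n",
              object@ploidy, object@plexity, object@nLow, object@nHigh,
              object@depthLow, object@depthHigh, object@replicates))
  th <- object@thresholds
  cat(sprintf("  95%% [%.4f, %.4f]; 99%% [%.4f, %.4f]\n",
              th["lower", "95"], th["upper", "95"],
              th["lower", "99"], th["upper", "99"]))
})

setMethod("show", "BsaVariantSet", function(object) {
  cat(sprintf("BsaVariantSet with %d variants on %d sequence(s)\n",
              nrow(object), length(GenomeInfoDb::seqlevels(object))))
  rd <- SummarizedExperiment::rowData(object)
  if ("donor" %in% colnames(rd))
    cat(sprintf("  classified: donor %s, plexity %s\n",
                paste(unique(rd$donor), collapse = "/"),
                paste(unique(rd$plexity), collapse = "/")))
  if ("delta" %in% colnames(rd))
    cat(sprintf("  scored: %d sig95, %d sig99\n",
                sum(rd$sig95), sum(rd$sig99)))
  invisible(NULL)
})
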