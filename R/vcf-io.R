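#' Read a multi-sample VCF into a BsaVariantSet
#'
#' Reads a VCF v4.x file (plain or bgzipped) with
#' \code{VariantAnnotation::readVcf} and extracts per-sample reference/alternate
#' allele depths from the \code{AD} genotype field (falling back to
#' freebayes-style \code{RO}/\code{AO} when \code{AD} is absent; sites with
#' neither are skipped with a warning). Records are sorted by chromosome (in
#' VCF header order) and position. Missing depth at any role is recorded as
#' (0, 0), so such sites fall to the minimum-depth filter.
#'
#' @param vcfPath path to the VCF file.
#' @param sampleMap named character vector mapping the roles \code{P1},
#'   \code{P2}, \code{BULK_LOW}, \code{BULK_HIGH} to sample names present in
#'   the VCF header.
#' @param multiallelic policy for multiallelic sites: \code{"drop"} (default)
#'   removes them, \code{"split"} expands them into one biallelic record per
#'   alternate allele.
#' @return A \code{\linkS4class{BsaVariantSet}}.
#' @export
readBsaVcf <- function(vcfPath, sampleMap, multiallelic = c("drop", "split")) {
  multiallelic <- match.arg(multiallelic)
  if (!all(.bsaRoles %in% names(sampleMap)))
    stop("sampleMap must name all roles: ", paste(.bsaRoles, collapse = ", "))
  hdr <- VariantAnnotation::scanVcfHeader(vcfPath)
  vcfSamples <- VariantAnnotation::samples(hdr)
  missing <- setdiff(unname(sampleMap[.bsaRoles]), vcfSamples)
  if (length(missing))
    stop("sample(s) not found in VCF header: ", paste(missing, collapse = ", "))
  vcf <- VariantAnnotation::readVcf(vcfPath)
  nAlt <- lengths(VariantAnnotation::alt(vcf))
  if (multiallelic == "drop") {
    vcf <- vcf[nAlt == 1L]
  } else {
    vcf <- VariantAnnotation::expand(vcf)
  }
  if (nrow(vcf) == 0L)
    return(.emptyVariantSet())

  gtf <- VariantAnnotation::geno(vcf)
  nm <- names(gtf)
  n <- nrow(vcf)
  sm <- unname(sampleMap[.bsaRoles])
  refd <- matrix(0L, n, 4L)
  altd <- matrix(0L, n, 4L)
  ok <- rep(TRUE, n)
  if ("AD" %in% nm) {
    ad <- gtf$AD
    for (j in seq_len(4L)) {
      d <- .adPair(ad, sm[j], n)
      refd[, j] <- d$ref
      altd[, j] <- d$alt
      ok <- ok & d$ok
    }
  } else if (all(c("RO", "AO") %in% nm)) {
    for (j in seq_len(4L)) {
      ro <- suppressWarnings(as.integer(gtf$RO[, sm[j]]))
      ao <- gtf$AO
      aoj <- if (is.list(ao) || length(dim(ao)) == 3L)
        vapply(seq_len(n), function(i) .firstInt(ao[i, sm[j]][[1]]), integer(1))
      else suppressWarnings(as.integer(ao[, sm[j]]))
      refd[, j] <- ifelse(is.na(ro), 0L, ro)
      altd[, j] <- ifelse(is.na(aoj), 0L, aoj)
      ok <- ok & !(is.na(ro) & is.na(aoj))
    }
  } else {
    warning("VCF has neither AD nor RO/AO genotype fields; all sites skipped")
    return(.emptyVariantSet())
  }
  if (any(!ok)) {
    warning(sum(!ok), " site(s) skipped: malformed or absent depth fields")
    vcf <- vcf[ok]
    refd <- refd[ok, , drop = FALSE]
    altd <- altd[ok, , drop = FALSE]
  }
  if (nrow(vcf) == 0L)
    return(.emptyVariantSet())

  rr <- SummarizedExperiment::rowRanges(vcf)
  av <- VariantAnnotation::alt(vcf)
  if (!methods::is(av, "XStringSet")) av <- unlist(av)
  gr <- GenomicRanges::GRanges(
    GenomeInfoDb::seqnames(rr),
    IRanges::IRanges(GenomicRanges::start(rr), width = 1L),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(av))
  o <- order(as.integer(GenomeInfoDb::seqnames(gr)), GenomicRanges::start(gr))
  BsaVariantSet(gr[o], refd[o, , drop = FALSE], altd[o, , drop = FALSE])
}

## Extract (ref, alt) depth pairs for one sample from a readVcf AD container,
## which is a matrix of lists or a 3-d array depending on alt multiplicity.
.adPair <- function(ad, sample, n) {
  out <- list(ref = integer(n), alt = integer(n), ok = rep(TRUE, n))
  if (length(dim(ad)) == 3L) {
    out$ref <- suppressWarnings(as.integer(ad[, sample, 1L]))
    out$alt <- suppressWarnings(as.integer(ad[, sample, 2L]))
  } else {
    col <- ad[, sample]
    for (i in seq_len(n)) {
      v <- suppressWarnings(as.integer(col[[i]]))
      if (length(v) >= 2L && !anyNA(v[1:2])) {
        out$ref[i] <- v[1L]; out$alt[i] <- v[2L]
      } else {
        out$ok[i] <- FALSE
      }
    }
  }
  bad <- is.na(out$ref) | is.na(out$alt)
  out$ref[bad] <- 0L; out$alt[bad] <- 0L
  ## a fully missing AD (e.g. ".") is a missing genotype, recorded as (0,0)
  out
}

.firstInt <- function(v) {
  v <- suppressWarnings(as.integer(v))
  if (length(v) && !is.na(v[1L])) v[1L] else NA_integer_
}

.emptyVariantSet <- function() {
  gr <- GenomicRanges::GRanges(ref = character(0), alt = character(0))
  m <- matrix(integer(0), 0, 4L, dimnames = list(NULL, .bsaRoles))
  BsaVariantSet(gr, m, m)
}

#' Apply site-level filters
#'
#' Retains sites whose total read depth (ref + alt) is at least
#' \code{minDepth} in all four roles and whose ref/alt length difference is at
#' most \code{maxIndelLength} bp. Order is preserved; the operation is
#' idempotent.
#'
#' @param x A \code{\linkS4class{BsaVariantSet}}.
#' @param minDepth minimum per-role total depth (default 50).
#' @param maxIndelLength maximum indel length in bp (default 71, i.e. indels
#'   must be shorter than 72 bp).
#' @return The filtered \code{BsaVariantSet}.
#' @export
filterVariants <- function(x, minDepth = 50, maxIndelLength = 71) {
  stopifnot(minDepth >= 1, maxIndelLength >= 0)
  if (nrow(x) == 0L) return(x)
  td <- totalDepth(x)
  keep <- apply(td >= minDepth, 1L, all) & variantLength(x) <= maxIndelLength
  x[keep, ]
}

#' Write scored variants as TSV
#'
#' Writes one row per scored variant with columns \code{chrom}, \code{pos},
#' \code{donor}, \code{plexity}, \code{idx_low}, \code{idx_high},
#' \code{delta}, \code{p_value}, \code{sig95}, \code{sig99}; floating point
#' values are printed with 4 decimals.
#'
#' @param x a scored \code{\linkS4class{BsaVariantSet}} (see
#'   \code{\link{scoreVariants}}).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeScoredTsv <- function(x, path) {
  rd <- SummarizedExperiment::rowData(x)
  need <- c("donor", "plexity", "idxLow", "idxHigh", "delta", "p", "sig95", "sig99")
  if (nrow(x) > 0L && !all(need %in% colnames(rd)))
    stop("variants are not scored; run classifyVariants() and scoreVariants() first")
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(x)),
    pos = GenomicRanges::start(x),
    donor = if (nrow(x)) rd$donor else character(0),
    plexity = if (nrow(x)) rd$plexity else integer(0),
    idx_low = sprintf("%.4f", if (nrow(x)) rd$idxLow else numeric(0)),
    idx_high = sprintf("%.4f", if (nrow(x)) rd$idxHigh else numeric(0)),
    delta = sprintf("%.4f", if (nrow(x)) rd$delta else numeric(0)),
    p_value = sprintf("%.4f", if (nrow(x)) rd$p else numeric(0)),
    sig95 = if (nrow(x)) rd$sig95 else logical(0),
    sig99 = if (nrow(x)) rd$sig99 else logical(0),
    stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    df <- df[0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-length table
#'
#' Two-column TSV: chromosome name, length in bp. No header required; a header
#' line whose second field is non-numeric is skipped.
#'
#' @param path file path.
#' @return Named numeric vector of lengths.
#' @export
readChromLengths <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df[1, 2]))))
    df <- df[-1, , drop = FALSE]
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}
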