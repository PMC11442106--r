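#' Accessors for BsaVariantSet
#'
#' @param x A \code{\linkS4class{BsaVariantSet}}.
#' @return \code{refDepth}/\code{altDepth}: integer matrices (variants x
#'   roles). \code{totalDepth}: their sum. \code{variantLength}: absolute
#'   ref/alt length difference in bp (0 for a SNP).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("refDepth", function(x) standardGeneric("refDepth"))

#' @rdname accessors
#' @export
setGeneric("altDepth", function(x) standardGeneric("altDepth"))

#' @rdname accessors
#' @export
setGeneric("totalDepth", function(x) standardGeneric("totalDepth"))

#' @rdname accessors
#' @export
setGeneric("variantLength", function(x) standardGeneric("variantLength"))

#' @rdname accessors
setMethod("refDepth", "BsaVariantSet", function(x)
  SummarizedExperiment::assay(x, "refDepth"))

#' @rdname accessors
setMethod("altDepth", "BsaVariantSet", function(x)
  SummarizedExperiment::assay(x, "altDepth"))

#' @rdname accessors
setMethod("totalDepth", "BsaVariantSet", function(x)
  refDepth(x) + altDepth(x))

#' @rdname accessors
setMethod("variantLength", "BsaVariantSet", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  abs(nchar(rd$ref) - nchar(rd$alt))
})
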