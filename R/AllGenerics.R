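#' @rdname MotifLibrary-accessors
#' @export
setGeneric("rabMotifs", function(x) standardGeneric("rabMotifs"))

#' @rdname MotifLibrary-accessors
#' @export
setGeneric("familyMotifs", function(x) standardGeneric("familyMotifs"))

#' @rdname MotifLibrary-accessors
#' @export
setGeneric("diagnosticMotifs", function(x) standardGeneric("diagnosticMotifs"))

#' @rdname StageExpressionSet-accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname StageExpressionSet-accessors
#' @export
setGeneric("flaggedGenes", function(x) standardGeneric("flaggedGenes"))

#' @rdname ColocResult-accessors
#' @export
setGeneric("overlapGreen", function(x) standardGeneric("overlapGreen"))

#' @rdname ColocResult-accessors
#' @export
setGeneric("overlapRed", function(x) standardGeneric("overlapRed"))

#' Accessors for MotifLibrary objects
#'
#' @param x a \linkS4class{MotifLibrary}.
#' @return \code{rabMotifs}: the 5 Rab motifs; \code{familyMotifs}: named list
#'   of other-family motif sets; \code{diagnosticMotifs}: named character
#'   vector of extra exact-match motifs.
#' @name MotifLibrary-accessors
#' @aliases rabMotifs,MotifLibrary-method familyMotifs,MotifLibrary-method
#'   diagnosticMotifs,MotifLibrary-method
NULL

setMethod("rabMotifs", "MotifLibrary", function(x) x@rabMotifs)
setMethod("familyMotifs", "MotifLibrary", function(x) x@familyMotifs)
setMethod("diagnosticMotifs", "MotifLibrary", function(x) x@diagnosticMotifs)

#' Accessors for StageExpressionSet objects
#'
#' @param x a \linkS4class{StageExpressionSet}.
#' @return \code{intensities}: the genes x stages numeric matrix;
#'   \code{flaggedGenes}: ids of genes with missing stage values.
#' @name StageExpressionSet-accessors
#' @aliases intensities,StageExpressionSet-method
#'   flaggedGenes,StageExpressionSet-method
NULL

setMethod("intensities", "StageExpressionSet", function(x) x@intensities)
setMethod("flaggedGenes", "StageExpressionSet", function(x) x@flagged)

#' Accessors for ColocResult objects
#'
#' @param x a \linkS4class{ColocResult}.
#' @return the per-channel overlap fraction in [0,1].
#' @name ColocResult-accessors
#' @aliases overlapGreen,ColocResult-method overlapRed,ColocResult-method
NULL

setMethod("overlapGreen", "ColocResult", function(x) x@overlapGreen)
setMethod("overlapRed", "ColocResult", function(x) x@overlapRed)
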