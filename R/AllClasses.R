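#' @import methods
#' @importFrom stats setNames rpois runif rnorm rlnorm quantile sd
#' @importFrom utils read.delim write.table head combn
NULL

#' MotifLibrary: diagnostic motif sets for small-GTPase family discrimination
#'
#' Holds the five Rab-family (RabF) motifs, per-family consensus motifs for
#' the other small-GTPase classes (Ras, Rho, Arf/Sar, Ran), and any extra
#' named diagnostic motifs (e.g. the WDIAGQE motif shared by a deeply
#' conserved clade associated with lysosome-related organelles).
#'
#' @slot rabMotifs character vector of exactly 5 Rab motifs, each 4-7
#'   uppercase residues, in N- to C-terminal structural order.
#' @slot familyMotifs named list; one character vector of motifs per
#'   non-Rab family.
#' @slot diagnosticMotifs named character vector of additional exact-match
#'   motifs.
#' @export
setClass("MotifLibrary",
  representation(
    rabMotifs = "character",
    familyMotifs = "list",
    diagnosticMotifs = "character"
  )
)

setValidity("MotifLibrary", function(object) {
  msgs <- character()
  aa <- "^[ACDEFGHIKLMNPQRSTVWY]+$"
  if (length(object@rabMotifs) != 5L)
    msgs <- c(msgs, "rabMotifs must contain exactly 5 motifs")
  if (!all(grepl(aa, object@rabMotifs)))
    msgs <- c(msgs, "rabMotifs must use the uppercase one-letter amino-acid alphabet")
  if (!all(nchar(object@rabMotifs) >= 4L & nchar(object@rabMotifs) <= 7L))
    msgs <- c(msgs, "each Rab motif must be 4-7 residues long")
  if (length(object@familyMotifs)) {
    if (is.null(names(object@familyMotifs)) || any(!nzchar(names(object@familyMotifs))))
      msgs <- c(msgs, "familyMotifs must be a named list")
    if (any(vapply(object@familyMotifs, length, 1L) < 1L))
      msgs <- c(msgs, "every family must have at least one motif")
    if (!all(vapply(object@familyMotifs, function(m) all(grepl(aa, m)), TRUE)))
      msgs <- c(msgs, "family motifs must use the amino-acid alphabet")
  }
  if (length(object@diagnosticMotifs) && is.null(names(object@diagnosticMotifs)))
    msgs <- c(msgs, "diagnosticMotifs must be named")
  if (length(msgs)) msgs else TRUE
})

#' StageExpressionSet: expression intensities over the fixed stage grid
#'
#' A genes x stages matrix of microarray-style signal intensities (arbitrary
#' units) over the 20-stage grid spanning growth (Ll, Lm, Lh), starvation
#' (S0..S24, 7 points) and conjugation (C0..C18, 10 points).
#'
#' @slot intensities numeric matrix, rownames = gene ids, colnames = the 20
#'   stage labels in canonical order.
#' @slot flagged character vector of gene ids with missing values.
#' @export
setClass("StageExpressionSet",
  representation(intensities = "matrix", flagged = "character")
)

setValidity("StageExpressionSet", function(object) {
  msgs <- character()
  if (!is.numeric(object@intensities))
    msgs <- c(msgs, "intensities must be numeric")
  if (!identical(colnames(object@intensities), stageSet()$stage))
    msgs <- c(msgs, "columns must be the 20 canonical stage labels in order")
  if (nrow(object@intensities) > 0L &&
      (is.null(rownames(object@intensities)) ||
       anyDuplicated(rownames(object@intensities))))
    msgs <- c(msgs, "rownames must be unique gene ids")
  if (!all(object@flagged %in% rownames(object@intensities)))
    msgs <- c(msgs, "flagged ids must be present in the matrix")
  if (length(msgs)) msgs else TRUE
})

#' ColocResult: thresholded-mask overlap fractions for one two-channel image
#'
#' @slot overlapGreen,overlapRed fraction of each channel's above-threshold
#'   intensity that falls in pixels above threshold in both channels; in [0,1].
#' @slot maskPixels named integer vector (green, red, and_mask).
#' @slot thresholds named numeric vector of the intensity thresholds applied.
#' @export
setClass("ColocResult",
  representation(
    overlapGreen = "numeric",
    overlapRed = "numeric",
    maskPixels = "integer",
    thresholds = "numeric"
  )
)

setValidity("ColocResult", function(object) {
  msgs <- character()
  ok <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
  if (!ok(object@overlapGreen)) msgs <- c(msgs, "overlapGreen must be a single value in [0,1]")
  if (!ok(object@overlapRed)) msgs <- c(msgs, "overlapRed must be a single value in [0,1]")
  px <- object@maskPixels
  if (!all(c("green", "red", "and_mask") %in% names(px)))
    msgs <- c(msgs, "maskPixels must name green, red and and_mask counts")
  else if (px[["and_mask"]] > min(px[["green"]], px[["red"]]))
    msgs <- c(msgs, "AND mask cannot exceed either channel mask")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "MotifLibrary", function(object) {
  cat("MotifLibrary\n")
  cat("  Rab motifs:       ", paste(object@rabMotifs, collapse = " "), "\n")
  for (fam in names(object@familyMotifs))
    cat(sprintf("  %-18s%s\n", paste0(fam, ":"),
                paste(object@familyMotifs[[fam]], collapse = " ")))
  if (length(object@diagnosticMotifs))
    cat("  diagnostic:       ",
        paste(sprintf("%s=%s", names(object@diagnosticMotifs),
                      object@diagnosticMotifs), collapse = " "), "\n")
})

setMethod("show", "StageExpressionSet", function(object) {
  cat(sprintf("StageExpressionSet: %d gene(s) x %d stages\n",
              nrow(object@intensities), ncol(object@intensities)))
  if (length(object@flagged))
    cat("  flagged (missing values):", paste(object@flagged, collapse = ", "), "\n")
})

setMethod("show", "ColocResult", function(object) {
  cat(sprintf(
    "ColocResult: overlap green = %.3f, red = %.3f (mask px: G=%d R=%d AND=%d)\n",
    object@overlapGreen, object@overlapRed,
    object@maskPixels[["green"]], object@maskPixels[["red"]],
    object@maskPixels[["and_mask"]]))
})
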