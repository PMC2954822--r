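## Thresholded-mask colocalization for two-channel single-plane images
## (e.g. GFP-Rab vs the endocytic tracer FM4-64).

.checkImage <- function(img) {
  if (!is.matrix(img) || !is.numeric(img) || !length(img))
    stop("empty image: expected a nonempty numeric matrix")
  if (any(!is.finite(img))) stop("image contains non-finite values")
  if (any(img < 0)) stop("image intensities must be nonnegative")
  img
}

#' Read a grayscale channel image
#'
#' Supports 8/16-bit grayscale TIFF or PNG (first channel used if the file
#' holds several) and whitespace-delimited plain-matrix text.
#'
#' @param path file path; format inferred from the extension
#'   (\code{.tif/.tiff}, \code{.png}, anything else = plain matrix text).
#' @return numeric intensity matrix.
#' @export
readChannelImage <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
    else if (ext == "png") png::readPNG(path)
    else as.matrix(read.table(path))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  dimnames(img) <- NULL
  .checkImage(img)
}

#' Threshold an intensity image into a boolean mask
#'
#' Pixels strictly above the threshold are TRUE; the strict inequality
#' makes constant regions deterministic (a constant image thresholded at
#' its own value yields an empty mask). Thresholding is how the analysis
#' restricts itself to the brightest labeled structures in each channel.
#'
#' @param img numeric intensity matrix.
#' @param method \code{"fraction_of_max"} (threshold = min + value * (max -
#'   min), i.e. a fraction of the dynamic range), \code{"absolute"}, or
#'   \code{"quantile"}.
#' @param value fraction in [0,1] for \code{fraction_of_max} and
#'   \code{quantile}; a nonnegative intensity for \code{absolute}.
#' @return logical matrix; the applied intensity threshold is recorded in
#'   the \code{"threshold"} attribute.
#' @export
thresholdMask <- function(img, method = c("fraction_of_max", "absolute",
                                          "quantile"), value = 0.5) {
  method <- match.arg(method)
  .checkImage(img)
  thr <- switch(method,
    fraction_of_max = {
      if (value < 0 || value > 1) stop("fraction_of_max value must be in [0,1]")
      ## relative to the dynamic range, so a constant image has an empty mask
      min(img) + value * (max(img) - min(img))
    },
    absolute = {
      if (value < 0) stop("absolute threshold must be >= 0")
      value
    },
    quantile = {
      if (value < 0 || value > 1) stop("quantile value must be in [0,1]")
      ## order-statistic threshold: keep the top (1-value) fraction
      stats::quantile(img, probs = value, type = 1L, names = FALSE)
    })
  mask <- img > thr
  attr(mask, "threshold") <- unname(thr)
  mask
}

#' Overlap coefficients from thresholded masks
#'
#' The overlap for a channel is the fraction of that channel's
#' above-threshold signal intensity residing in pixels above threshold in
#' both channels: \code{sum(green[AND]) / sum(green[green_mask])}, and
#' conversely for red. Identical channels with identical masks register
#' 1.0; disjoint masks register 0. An empty channel mask yields 0 for that
#' channel. The published mean-intensity-ratio variant (average intensity
#' in the AND mask over average intensity in the channel mask) is available
#' with \code{method = "mean_ratio"}, but is not bounded by 1.
#'
#' @param green,red numeric intensity matrices of matching dimensions.
#' @param greenMask,redMask logical masks (e.g. from
#'   \code{\link{thresholdMask}}).
#' @param method \code{"intensity_fraction"} (default) or
#'   \code{"mean_ratio"}.
#' @return a \linkS4class{ColocResult}.
#' @export
overlapCoefficients <- function(green, red, greenMask, redMask,
                                method = c("intensity_fraction",
                                           "mean_ratio")) {
  method <- match.arg(method)
  .checkImage(green); .checkImage(red)
  if (!identical(dim(green), dim(red)) ||
      !identical(dim(green), dim(greenMask)) ||
      !identical(dim(green), dim(redMask)))
    stop("dimension mismatch between channels and masks")
  if (!is.logical(greenMask) || !is.logical(redMask))
    stop("masks must be logical")
  andMask <- greenMask & redMask
  ov <- function(img, mask) {
    if (!any(mask)) return(0)
    if (method == "intensity_fraction")
      sum(img[andMask]) / sum(img[mask])
    else {
      if (!any(andMask)) return(0)
      mean(img[andMask]) / mean(img[mask])
    }
  }
  og <- ov(green, greenMask)
  or_ <- ov(red, redMask)
  thrG <- attr(greenMask, "threshold")
  thrR <- attr(redMask, "threshold")
  thr <- c(green = if (is.null(thrG)) NA_real_ else thrG,
           red = if (is.null(thrR)) NA_real_ else thrR)
  new("ColocResult",
      overlapGreen = min(og, 1), overlapRed = min(or_, 1),
      maskPixels = c(green = sum(greenMask), red = sum(redMask),
                     and_mask = sum(andMask)),
      thresholds = thr)
}

#' Quantify colocalization over a set of cells
#'
#' Thresholds each channel of each cell independently and computes overlap
#' coefficients; cells whose channels disagree in size are reported as
#' errors without stopping the rest. Summaries over fewer than 4 cells are
#' refused unless \code{force = TRUE} (a warning is issued), reflecting the
#' minimum cells-per-line analyzed in practice.
#'
#' @param cells list of cells, each a list with elements \code{green} and
#'   \code{red} (numeric matrices).
#' @param thresholdMethod,thresholdValue per-channel thresholding config,
#'   passed to \code{\link{thresholdMask}}.
#' @param method overlap formula, see \code{\link{overlapCoefficients}}.
#' @param force allow a summary over fewer than 4 cells.
#' @return list with \code{perCell} (data.frame: cell, overlap_green,
#'   overlap_red, error) and \code{summary} (mean and sd per channel, or
#'   NULL when refused).
#' @export
quantifyCells <- function(cells, thresholdMethod = "fraction_of_max",
                          thresholdValue = 0.5,
                          method = "intensity_fraction", force = FALSE) {
  if (!length(cells)) stop("empty cell list")
  rows <- lapply(seq_along(cells), function(i) {
    res <- tryCatch({
      g <- cells[[i]]$green; r <- cells[[i]]$red
      gm <- thresholdMask(g, thresholdMethod, thresholdValue)
      rm_ <- thresholdMask(r, thresholdMethod, thresholdValue)
      cc <- overlapCoefficients(g, r, gm, rm_, method)
      data.frame(cell = i, overlap_green = overlapGreen(cc),
                 overlap_red = overlapRed(cc), error = NA_character_)
    }, error = function(e)
      data.frame(cell = i, overlap_green = NA_real_, overlap_red = NA_real_,
                 error = conditionMessage(e)))
    res
  })
  perCell <- do.call(rbind, rows)
  ok <- perCell[is.na(perCell$error), ]
  summary <- NULL
  if (nrow(ok) < 4L && !force) {
    warning("fewer than 4 analyzable cells; summary refused (use force = TRUE)")
  } else if (nrow(ok) >= 1L) {
    summary <- data.frame(
      channel = c("green", "red"),
      mean = c(mean(ok$overlap_green), mean(ok$overlap_red)),
      sd = c(stats::sd(ok$overlap_green), stats::sd(ok$overlap_red)),
      n = nrow(ok))
    if (nrow(ok) == 1L) summary$sd <- 0
  }
  list(perCell = perCell, summary = summary)
}
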