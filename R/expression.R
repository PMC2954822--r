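## Stage-grid expression analysis over the fixed 20-stage grid:
## growth (Ll/Lm/Lh), starvation (S0..S24) and conjugation (C0..C18).

#' The canonical stage grid
#'
#' Growth cultures at three densities (Ll exponential, Lm deceleratory, Lh
#' stationary), seven starvation time points (hours), and ten conjugation
#' time points at 2 h spacing.
#'
#' @return data.frame with columns \code{stage} (20 unique labels, in
#'   canonical order) and \code{condition} (\code{growth},
#'   \code{starvation}, \code{conjugation}).
#' @export
stageSet <- function() {
  data.frame(
    stage = c("Ll", "Lm", "Lh",
              paste0("S", c(0, 3, 6, 9, 12, 15, 24)),
              paste0("C", seq(0, 18, by = 2))),
    condition = rep(c("growth", "starvation", "conjugation"), c(3L, 7L, 10L))
  )
}

.stagesOf <- function(condition) {
  ss <- stageSet()
  if (!condition %in% ss$condition) stop("unknown condition: ", condition)
  ss$stage[ss$condition == condition]
}

#' Construct a StageExpressionSet from a genes x stages matrix
#'
#' @param mat numeric matrix; colnames must be the 20 stage labels (any
#'   order; columns are reordered canonically), rownames unique gene ids.
#' @return a \linkS4class{StageExpressionSet}; genes with missing values
#'   are flagged, not dropped.
#' @export
StageExpressionSet <- function(mat) {
  ss <- stageSet()
  missing <- setdiff(ss$stage, colnames(mat))
  if (length(missing))
    stop("missing stage column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(colnames(mat), ss$stage)
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  mat <- mat[, ss$stage, drop = FALSE]
  flagged <- as.character(rownames(mat)[apply(mat, 1L, anyNA)])
  new("StageExpressionSet", intensities = mat, flagged = flagged)
}

#' Load expression profiles from TSV
#'
#' Expects a header with a gene-id column (first column) plus the 20 stage
#' labels in any order. Non-numeric cells raise an error; rows with missing
#' stages are flagged, not dropped.
#'
#' @param path TSV file path.
#' @return a \linkS4class{StageExpressionSet}.
#' @export
loadExpression <- function(path) {
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  ids <- df[[1L]]
  df <- df[, -1L, drop = FALSE]
  num <- matrix(NA_real_, nrow(df), ncol(df),
                dimnames = list(ids, colnames(df)))
  for (j in seq_along(df)) {
    v <- trimws(df[[j]])
    nv <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(nv) & !(v == "" | toupper(v) == "NA"))
    if (length(bad))
      stop("non-numeric cell in column ", colnames(df)[j], ", row ", bad[1L])
    num[, j] <- nv
  }
  StageExpressionSet(num)
}

#' Write a StageExpressionSet as TSV
#'
#' @param x a \linkS4class{StageExpressionSet}.
#' @param path output path.
#' @export
writeExpression <- function(x, path) {
  df <- data.frame(gene = rownames(intensities(x)), intensities(x),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Is a gene expressed above background in a condition?
#'
#' TRUE iff any stage value within the condition strictly exceeds the
#' background threshold.
#'
#' @param profile named numeric vector over the 20 stages, or a single-row
#'   subset of \code{intensities()}.
#' @param backgroundThreshold positive intensity threshold (arbitrary
#'   units).
#' @param condition one of \code{"growth"}, \code{"starvation"},
#'   \code{"conjugation"}.
#' @return logical.
#' @export
callExpressed <- function(profile, backgroundThreshold, condition) {
  if (backgroundThreshold <= 0) stop("`backgroundThreshold` must be > 0")
  st <- .stagesOf(condition)
  any(profile[st] > backgroundThreshold, na.rm = TRUE)
}

#' Find discrete expression peaks within condition blocks
#'
#' A stage is a discrete peak when its value strictly exceeds
#' \code{foldThreshold} times the maximum over all other (non-excluded)
#' stages of the same condition — the strongest reading of a ">2-fold peak
#' at a distinct time point". At most one peak per condition can satisfy
#' this. S0 is excluded by default because the starvation-onset point
#' coincides with a medium change and is hard to interpret.
#'
#' @inheritParams callExpressed
#' @param foldThreshold fold-change threshold, > 1 (default 2).
#' @param excludeStages stages ignored entirely (default \code{"S0"}).
#' @return data.frame with columns condition, stage, fold (peak value over
#'   the best other in-condition value); zero rows when no stage
#'   qualifies. An all-zero block yields no peak.
#' @export
findDiscretePeaks <- function(profile, foldThreshold = 2.0,
                              excludeStages = "S0") {
  if (foldThreshold <= 1) stop("`foldThreshold` must be > 1")
  ss <- stageSet()
  out <- list()
  for (cond in unique(ss$condition)) {
    st <- setdiff(.stagesOf(cond), excludeStages)
    v <- profile[st]
    if (length(v) < 2L || all(is.na(v))) next
    top <- which.max(v)
    rest <- max(v[-top], na.rm = TRUE)
    if (is.na(v[top]) || v[top] <= 0) next
    if (rest <= 0) {
      fold <- Inf
    } else {
      fold <- v[top] / rest
    }
    if (fold > foldThreshold)
      out[[length(out) + 1L]] <- data.frame(
        condition = cond, stage = st[top], fold = unname(fold))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(condition = character(), stage = character(),
                      fold = numeric())
  res
}

#' Cohort-level expression summary
#'
#' Computes, over a set of profiles: the fraction expressed above background
#' per condition, the fraction whose global maximum falls in each
#' condition, and per-stage discrete-peak tallies.
#'
#' @param x a \linkS4class{StageExpressionSet}.
#' @param backgroundThreshold background intensity (default 1, arbitrary
#'   units).
#' @param foldThreshold,excludeStages passed to
#'   \code{\link{findDiscretePeaks}}.
#' @return list with \code{fraction_expressed} (named by condition),
#'   \code{fraction_max_in} (named by condition), \code{peak_tally}
#'   (named integer, by stage), and \code{peaks} (the per-gene peak table).
#' @export
summarizeCohort <- function(x, backgroundThreshold = 1,
                            foldThreshold = 2.0, excludeStages = "S0") {
  mat <- intensities(x)
  if (!nrow(mat)) stop("empty input: no expression profiles")
  ss <- stageSet()
  conds <- unique(ss$condition)
  fracExpr <- vapply(conds, function(cond)
    mean(vapply(seq_len(nrow(mat)), function(i)
      callExpressed(mat[i, ], backgroundThreshold, cond), TRUE)),
    numeric(1))
  globalMaxCond <- apply(mat, 1L, function(v) {
    if (all(is.na(v)) || max(v, na.rm = TRUE) <= 0) return(NA_character_)
    ss$condition[which.max(v)]
  })
  fracMax <- vapply(conds, function(cond)
    mean(!is.na(globalMaxCond) & globalMaxCond == cond), numeric(1))
  peaks <- do.call(rbind, lapply(rownames(mat), function(g) {
    p <- findDiscretePeaks(mat[g, ], foldThreshold, excludeStages)
    if (nrow(p)) cbind(gene = g, p) else NULL
  }))
  if (is.null(peaks))
    peaks <- data.frame(gene = character(), condition = character(),
                        stage = character(), fold = numeric())
  tally <- table(factor(peaks$stage, levels = ss$stage))
  list(
    fraction_expressed = fracExpr,
    fraction_max_in = fracMax,
    peak_tally = setNames(as.integer(tally), names(tally)),
    peaks = peaks
  )
}
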