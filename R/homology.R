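## Pairwise alignment and reciprocal-best-hit orthology. Scoring follows
## BLAST-like conventions: BLOSUM62, affine gaps costing
## gapOpen + L * gapExtend for a gap of length L.

.checkAlnSeq <- function(x, alphabetPattern) {
  if (length(x) != 1L || !is.character(x) || !nzchar(x))
    stop("zero-length or non-character sequence")
  if (!grepl(alphabetPattern, x))
    stop("invalid alphabet in sequence: ", substr(x, 1, 20))
  x
}

.substMatrix <- function(substitutionMatrix) {
  if (is.matrix(substitutionMatrix)) return(substitutionMatrix)
  ## named matrices shipped with Biostrings (BLOSUM62, PAM250, ...)
  get(data(list = substitutionMatrix, package = "Biostrings",
           envir = environment()))
}

#' Optimal pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch (global, end gaps penalized) or Smith-Waterman (local)
#' alignment via dynamic programming, the native stand-in for a
#' database-search scoring step.
#'
#' @param a,b amino-acid sequences.
#' @param mode \code{"global"} or \code{"local"}.
#' @param substitutionMatrix a numeric scoring matrix or the name of one
#'   shipped with Biostrings (default \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend nonnegative penalties; a gap of length L costs
#'   \code{gapOpen + L * gapExtend}.
#' @return list with \code{score}, \code{alignedA}, \code{alignedB} (gapped
#'   strings of equal length) and \code{mode}. Local scores are floored at
#'   0 (empty alignment).
#' @examples
#' alignPair("IGVDFKLQIW", "IGVDFKLQIW")$score
#' @export
alignPair <- function(a, b, mode = c("global", "local"),
                      substitutionMatrix = "BLOSUM62",
                      gapOpen = 11, gapExtend = 1) {
  mode <- match.arg(mode)
  pat <- "^[ACDEFGHIKLMNPQRSTVWYBZX*]+$"
  .checkAlnSeq(a, pat); .checkAlnSeq(b, pat)
  if (gapOpen < 0 || gapExtend < 0) stop("gap penalties must be >= 0")
  mat <- .substMatrix(substitutionMatrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = mode, substitutionMatrix = mat,
    gapOpening = gapOpen, gapExtension = gapExtend)
  score <- Biostrings::score(aln)
  alignedA <- as.character(Biostrings::alignedPattern(aln))
  alignedB <- as.character(Biostrings::alignedSubject(aln))
  if (mode == "local" && score < 0) {
    score <- 0
    alignedA <- alignedB <- ""
  }
  list(score = unname(score), alignedA = unname(alignedA),
       alignedB = unname(alignedB), mode = mode)
}

#' Exhaustive-enumeration alignment score (reference implementation)
#'
#' Computes the optimal affine-gap alignment score by depth-first
#' enumeration of every monotone alignment path, with no dynamic-programming
#' table. Exponential in sequence length; intended as an independent
#' cross-check of \code{\link{alignPair}} on short sequences (roughly
#' length <= 10).
#'
#' @inheritParams alignPair
#' @return the optimal score (a single number).
#' @export
bruteForceAlignScore <- function(a, b, mode = c("global", "local"),
                                 substitutionMatrix = "BLOSUM62",
                                 gapOpen = 11, gapExtend = 1) {
  mode <- match.arg(mode)
  mat <- .substMatrix(substitutionMatrix)
  alpha <- rownames(mat)
  ia <- match(strsplit(a, "")[[1L]], alpha)
  ib <- match(strsplit(b, "")[[1L]], alpha)
  if (anyNA(ia) || anyNA(ib)) stop("sequence letters missing from matrix")
  brute_align(ia - 1L, ib - 1L, mat, gapOpen, gapExtend,
              local = identical(mode, "local"))
}

#' Percent identity between two sequences
#'
#' Identity is computed over a global alignment. With the default
#' \code{"gapped"} denominator every aligned column counts (gap-gap columns
#' cannot occur in a pairwise alignment); with \code{"ungapped"} only
#' columns where both sequences have a residue count.
#'
#' @inheritParams alignPair
#' @param denominator \code{"gapped"} (default) or \code{"ungapped"}.
#' @return identity as a percentage in [0, 100]; 0 for an empty overlap.
#' @export
percentIdentity <- function(a, b, substitutionMatrix = "BLOSUM62",
                            gapOpen = 11, gapExtend = 1,
                            denominator = c("gapped", "ungapped")) {
  denominator <- match.arg(denominator)
  aln <- alignPair(a, b, "global", substitutionMatrix, gapOpen, gapExtend)
  ca <- strsplit(aln$alignedA, "")[[1L]]
  cb <- strsplit(aln$alignedB, "")[[1L]]
  both <- ca != "-" & cb != "-"
  ident <- sum(ca == cb & both)
  denom <- if (denominator == "gapped") length(ca) else sum(both)
  if (denom == 0L) return(0)
  100 * ident / denom
}

#' Reciprocal best hits between two sequence sets
#'
#' All-vs-all pairwise alignment scores are computed and pairs (a, b) are
#' reported only when b is the unique top hit of a within set B and a is
#' the unique top hit of b within set A. Ties for the top score disqualify
#' the query (ambiguous orthology is excluded rather than broken
#' arbitrarily).
#'
#' @param setA,setB named character vectors or \code{AAStringSet}s with
#'   unique ids.
#' @inheritParams alignPair
#' @param selfHits when the two sets share ids, allow a sequence to match
#'   itself (default TRUE).
#' @return data.frame with columns id_a, id_b, score_ab, score_ba.
#' @export
reciprocalBestHits <- function(setA, setB, mode = "local",
                               substitutionMatrix = "BLOSUM62",
                               gapOpen = 11, gapExtend = 1,
                               selfHits = TRUE) {
  asVec <- function(x) {
    if (methods::is(x, "AAStringSet")) x <- setNames(as.character(x), names(x))
    if (!length(x)) stop("empty sequence set")
    if (is.null(names(x)) || anyDuplicated(names(x)))
      stop("duplicate or missing ids in sequence set")
    x
  }
  setA <- asVec(setA); setB <- asVec(setB)
  scores <- matrix(NA_real_, length(setA), length(setB),
                   dimnames = list(names(setA), names(setB)))
  for (i in seq_along(setA))
    for (j in seq_along(setB)) {
      if (!selfHits && names(setA)[i] == names(setB)[j]) next
      scores[i, j] <- alignPair(setA[[i]], setB[[j]], mode,
                                substitutionMatrix, gapOpen, gapExtend)$score
    }
  uniqueTop <- function(v) {
    top <- max(v, na.rm = TRUE)
    w <- which(v == top)
    if (length(w) == 1L) w else NA_integer_
  }
  bestAB <- apply(scores, 1L, uniqueTop)
  bestBA <- apply(scores, 2L, uniqueTop)
  pairs <- lapply(seq_along(setA), function(i) {
    j <- bestAB[i]
    if (is.na(j) || is.na(bestBA[j]) || bestBA[j] != i) return(NULL)
    data.frame(id_a = names(setA)[i], id_b = names(setB)[j],
               score_ab = scores[i, j], score_ba = scores[i, j])
  })
  out <- do.call(rbind, pairs)
  if (is.null(out))
    out <- data.frame(id_a = character(), id_b = character(),
                      score_ab = numeric(), score_ba = numeric())
  rownames(out) <- NULL
  out
}
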