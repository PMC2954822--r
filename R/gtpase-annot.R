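## Candidate classification: Rab vs Rab-like vs non-Rab.
## Positions are reported 1-based inclusive; internal arithmetic is on
## character vectors with 0-based offsets.

.AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.checkAASeq <- function(seq) {
  if (length(seq) != 1L || !is.character(seq))
    stop("`seq` must be a single character string")
  if (!nzchar(seq))
    stop("empty input: `seq` has zero length")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", seq))
    stop("invalid alphabet: `seq` contains non-amino-acid characters")
  invisible(seq)
}

## mismatch count of `motif` against every window of `chars`; integer(0) when
## the sequence is shorter than the motif
.windowMismatches <- function(chars, motif) {
  m <- strsplit(motif, "")[[1L]]
  k <- length(m)
  n <- length(chars)
  if (n < k) return(integer(0))
  mis <- integer(n - k + 1L)
  for (j in seq_len(k))
    mis <- mis + (chars[j:(n - k + j)] != m[j])
  mis
}

#' Scan a protein for the five Rab-family motifs
#'
#' Finds, for each RabF motif in turn, the best-scoring ungapped window with
#' at most \code{maxMismatch} mismatches. Because the motifs correspond to
#' ordered structural elements of the G domain, hits are required by default
#' to occur at strictly increasing positions (F1 before F2 ... before F5):
#' each motif is searched only downstream of the previous accepted hit.
#' Ties on mismatch count are broken by the leftmost window.
#'
#' @param seq single uppercase amino-acid string.
#' @param library a \linkS4class{MotifLibrary}.
#' @param maxMismatch maximum mismatches tolerated per motif (default 2).
#' @param requireOrder enforce strictly increasing hit positions
#'   (default TRUE).
#' @return data.frame with columns \code{motif_index} (1..5), \code{motif},
#'   \code{position} (1-based start), \code{mismatches}, and \code{score}
#'   (matched residues / motif length). Motifs with no qualifying window are
#'   absent; zero rows when nothing matches.
#' @examples
#' lib <- defaultMotifLibrary()
#' seq <- paste0("M", "IGVDF", strrep("A", 10), "KLQIW", strrep("A", 10),
#'               "RFRSIT", strrep("A", 10), "YYRGA", strrep("A", 10),
#'               "LVYDIT", "SNCC")
#' scanRabMotifs(seq, lib, maxMismatch = 0)
#' @export
scanRabMotifs <- function(seq, library = defaultMotifLibrary(),
                          maxMismatch = 2L, requireOrder = TRUE) {
  .checkAASeq(seq)
  if (maxMismatch < 0) stop("`maxMismatch` must be >= 0")
  chars <- strsplit(seq, "")[[1L]]
  motifs <- rabMotifs(library)
  out <- vector("list", length(motifs))
  minStart <- 1L
  for (i in seq_along(motifs)) {
    mis <- .windowMismatches(chars, motifs[i])
    cand <- which(mis <= maxMismatch)
    if (requireOrder) cand <- cand[cand >= minStart]
    if (!length(cand)) next
    best <- cand[which.min(mis[cand])]
    nmis <- mis[best]
    out[[i]] <- data.frame(
      motif_index = i, motif = motifs[i], position = best,
      mismatches = nmis,
      score = (nchar(motifs[i]) - nmis) / nchar(motifs[i])
    )
    if (requireOrder) minStart <- best + 1L
  }
  hits <- do.call(rbind, out)
  if (is.null(hits))
    hits <- data.frame(motif_index = integer(), motif = character(),
                       position = integer(), mismatches = integer(),
                       score = numeric())
  rownames(hits) <- NULL
  hits
}

## best matched-residue count over all windows, one value per motif
.bestMatchCounts <- function(chars, motifs) {
  vapply(motifs, function(m) {
    mis <- .windowMismatches(chars, m)
    if (!length(mis)) return(0L)
    nchar(m) - min(mis)
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign a candidate to a small-GTPase family by consensus-motif scoring
#'
#' Each family (Rab plus every family in the library) is scored as the sum,
#' over its motifs, of the best-window matched-residue counts anywhere in the
#' sequence. The winner must reach a floor of 40\% of its total possible
#' matched residues and beat the runner-up strictly (tie tolerance 0);
#' otherwise the call is \code{"unknown"}.
#'
#' @inheritParams scanRabMotifs
#' @param scoreFloor fraction of a family's maximum score required for a
#'   call (default 0.4).
#' @return list with elements \code{family} (one of Rab, the library
#'   families, or \code{"unknown"}), \code{perFamilyScore} (named numeric),
#'   \code{margin} (best minus second-best, on the normalized scale), and
#'   \code{tie} (TRUE when an exact tie forced \code{"unknown"}).
#' @export
classifyGtpaseFamily <- function(seq, library = defaultMotifLibrary(),
                                 maxMismatch = 2L, scoreFloor = 0.4) {
  .checkAASeq(seq)
  chars <- strsplit(seq, "")[[1L]]
  sets <- c(list(Rab = rabMotifs(library)), familyMotifs(library))
  raw <- vapply(sets, function(m) sum(.bestMatchCounts(chars, m)), numeric(1))
  maxPossible <- vapply(sets, function(m) sum(nchar(m)), numeric(1))
  norm <- raw / maxPossible  # comparable across families of unequal size
  ord <- order(norm, decreasing = TRUE)
  best <- ord[1L]
  margin <- norm[best] - norm[ord[2L]]
  tie <- margin == 0
  family <- if (norm[best] < scoreFloor || tie) "unknown" else names(sets)[best]
  list(family = family, perFamilyScore = raw, margin = unname(margin),
       tie = tie)
}

#' Test the C terminus for a prenylation motif
#'
#' Rab proteins are membrane-anchored through geranylgeranylation of
#' C-terminal cysteines. The final four residues are tested against the
#' anchored pattern set CC, CXC, CCX, CCXX, CXXX (X = any residue), in that
#' order, returning the first match.
#'
#' @param seq amino-acid string of length >= 4.
#' @return list with \code{pattern} (one of the five patterns or
#'   \code{"none"}) and \code{prenylatable} (TRUE iff a pattern matched).
#' @examples
#' classifyPrenylation("MKLSNGSNCC")   # CC
#' classifyPrenylation("MKLSNGCVLL")   # CXXX
#' classifyPrenylation("MKLSNGAKSQ")   # none
#' @export
classifyPrenylation <- function(seq) {
  .checkAASeq(seq)
  n <- nchar(seq)
  if (n < 4L) stop("too short: prenylation test needs at least 4 residues")
  tail4 <- strsplit(substr(seq, n - 3L, n), "")[[1L]]
  isC <- tail4 == "C"
  pattern <- if (isC[3L] && isC[4L]) "CC"
    else if (isC[2L] && isC[4L]) "CXC"
    else if (isC[2L] && isC[3L]) "CCX"
    else if (isC[1L] && isC[2L]) "CCXX"
    else if (isC[1L]) "CXXX"
    else "none"
  list(pattern = pattern, prenylatable = pattern != "none")
}

#' Call a candidate as Rab, Rab-like, or non-Rab
#'
#' Combines the family call, the RabF motif scan, and the prenylation test:
#' a candidate whose family call is not Rab (or that shows fewer than
#' \code{minMotifs} RabF motifs) is non-Rab; a Rab-family candidate with
#' sufficient motifs is a Rab when prenylatable and Rab-like when it lacks
#' the C-terminal cysteines.
#'
#' @inheritParams scanRabMotifs
#' @param minMotifs minimum number of RabF motif hits required (default 3).
#' @return list with \code{status} (\code{"Rab"}, \code{"Rab-like"} or
#'   \code{"non-Rab"}) and the evidence: \code{hits}, \code{familyCall},
#'   \code{prenylCall}.
#' @export
callRabStatus <- function(seq, library = defaultMotifLibrary(),
                          maxMismatch = 2L, minMotifs = 3L) {
  if (minMotifs < 1L || minMotifs > 5L)
    stop("`minMotifs` must be between 1 and 5")
  fam <- classifyGtpaseFamily(seq, library, maxMismatch)
  hits <- scanRabMotifs(seq, library, maxMismatch)
  pren <- classifyPrenylation(seq)
  status <- if (!identical(fam$family, "Rab") || nrow(hits) < minMotifs)
    "non-Rab"
  else if (pren$prenylatable) "Rab" else "Rab-like"
  list(status = status, hits = hits, familyCall = fam, prenylCall = pren)
}

#' Find all exact occurrences of a named diagnostic motif
#'
#' @inheritParams scanRabMotifs
#' @param motifName name of a motif in the library's diagnostic set
#'   (default \code{"WDIAGQE"}).
#' @return integer vector of 1-based start positions, ascending; empty when
#'   the motif is absent.
#' @export
detectDiagnosticMotif <- function(seq, motifName = "WDIAGQE",
                                  library = defaultMotifLibrary()) {
  .checkAASeq(seq)
  diag <- diagnosticMotifs(library)
  if (!motifName %in% names(diag))
    stop("unknown diagnostic motif: ", motifName)
  hits <- gregexpr(diag[[motifName]], seq, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

#' Annotate a set of candidate proteins
#'
#' Runs \code{\link{callRabStatus}} over a FASTA file or
#' \code{\link[Biostrings]{AAStringSet}} and returns the per-sequence report
#' the downstream summaries consume. Per-motif hits are attached as the
#' \code{"hits"} attribute (one row per motif occurrence).
#'
#' @param x path to a protein FASTA file, a named character vector, or an
#'   \code{AAStringSet}.
#' @inheritParams callRabStatus
#' @param reportFile optional path; when given, the report is also written
#'   as a TSV.
#' @return data.frame with columns id, family, n_motifs, prenyl_pattern,
#'   status.
#' @export
annotateSequences <- function(x, library = defaultMotifLibrary(),
                              maxMismatch = 2L, minMotifs = 3L,
                              reportFile = NULL) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readAAStringSet(x)
  if (methods::is(x, "AAStringSet"))
    x <- setNames(as.character(x), names(x))
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("sequences must carry unique names")
  calls <- lapply(x, callRabStatus, library = library,
                  maxMismatch = maxMismatch, minMotifs = minMotifs)
  report <- data.frame(
    id = names(x),
    family = vapply(calls, function(cc) cc$familyCall$family, ""),
    n_motifs = vapply(calls, function(cc) nrow(cc$hits), 0L),
    prenyl_pattern = vapply(calls, function(cc) cc$prenylCall$pattern, ""),
    status = vapply(calls, function(cc) cc$status, ""),
    row.names = NULL
  )
  hits <- do.call(rbind, lapply(names(x), function(id) {
    h <- calls[[id]]$hits
    if (nrow(h)) cbind(id = id, h) else NULL
  }))
  attr(report, "hits") <- hits
  if (!is.null(reportFile))
    write.table(report, reportFile, sep = "\t", quote = FALSE,
                row.names = FALSE)
  report
}
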