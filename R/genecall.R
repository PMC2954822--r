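## ORF prediction under the ciliate nuclear genetic code, in which UAA and
## UAG encode glutamine and UGA is the sole stop codon.

#' The ciliate nuclear genetic code
#'
#' Built from the standard code by reassigning TAA and TAG to glutamine,
#' leaving TGA as the only stop codon (NCBI translation table 6).
#'
#' @return named character(64); names are DNA codons, values one-letter
#'   amino acids, with \code{"*"} for the stop codon TGA.
#' @examples
#' ciliateGeneticCode()[c("TAA", "TAG", "TGA")]
#' @export
ciliateGeneticCode <- function() {
  code <- Biostrings::GENETIC_CODE
  code[["TAA"]] <- "Q"
  code[["TAG"]] <- "Q"
  code
}

.checkNASeq <- function(na) {
  if (length(na) != 1L || !is.character(na))
    stop("`na` must be a single character string")
  na <- toupper(gsub("U", "T", toupper(na)))
  if (!nzchar(na)) stop("empty input: nucleotide sequence has zero length")
  if (!grepl("^[ACGT]+$", na))
    stop("invalid alphabet: nucleotide sequence contains characters outside A/C/G/T/U")
  na
}

#' Translate a nucleotide sequence under the ciliate nuclear code
#'
#' TAA and TAG translate to Q. TGA either terminates translation
#' (\code{toFirstStop = TRUE}) or is rendered as \code{"*"}. A trailing
#' partial codon is ignored.
#'
#' @param na nucleotide string over A/C/G/T (U accepted, mapped to T).
#' @param frame reading frame, 1, 2 or 3.
#' @param toFirstStop stop at the first in-frame TGA (default TRUE).
#' @return amino-acid string (possibly empty).
#' @examples
#' translateCiliate("CAATAAATGTGA")  # "QQM"
#' @export
translateCiliate <- function(na, frame = 1L, toFirstStop = TRUE) {
  na <- .checkNASeq(na)
  if (!frame %in% 1:3) stop("`frame` must be 1, 2 or 3")
  n <- nchar(na)
  starts <- seq.int(frame, n - 2L, by = 3L)
  if (frame > n - 2L) return("")
  codons <- substring(na, starts, starts + 2L)
  aa <- unname(ciliateGeneticCode()[codons])
  if (toFirstStop) {
    stop_at <- which(aa == "*")
    if (length(stop_at)) aa <- aa[seq_len(stop_at[1L] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Predict the Rab open reading frame in an mRNA
#'
#' Mirrors manual ciliate gene-model curation: the transcript (UTRs
#' included) is translated in all three forward frames under the ciliate
#' code, and the coding frame is taken to be the one whose translation
#' carries the most RabF motif hits. The start codon is the nearest in-frame
#' ATG at or upstream of the first motif hit ("shortly upstream" of the
#' first conserved motif), optionally capped at \code{maxStartUpstream}
#' nucleotides; the stop is the first in-frame TGA downstream of the last
#' motif hit.
#'
#' @param mrna nucleotide string, length >= 60.
#' @param library a \linkS4class{MotifLibrary}.
#' @param maxMismatch mismatch tolerance passed to the motif scan.
#' @param maxStartUpstream optional cap (in nucleotides) on how far upstream
#'   of the first motif the start codon may lie; \code{Inf} = no cap.
#' @return list with \code{frame} (1..3), \code{start} and \code{stop}
#'   (1-based nucleotide positions of the initiator ATG and the terminating
#'   TGA), and \code{peptide} (the encoded protein, stop excluded).
#' @export
predictOrf <- function(mrna, library = defaultMotifLibrary(),
                       maxMismatch = 2L, maxStartUpstream = Inf) {
  mrna <- .checkNASeq(mrna)
  if (nchar(mrna) < 60L) stop("`mrna` must be at least 60 nt")
  ## full-length translations with internal stops rendered as "*"
  trans <- lapply(1:3, function(f) translateCiliate(mrna, f, toFirstStop = FALSE))
  scanFrame <- function(pep) {
    ## "*" is outside the amino-acid alphabet; count it as a mismatch by
    ## scanning on a sanitized copy
    clean <- gsub("\\*", "X", pep)
    chars <- strsplit(clean, "")[[1L]]
    motifs <- rabMotifs(library)
    hits <- lapply(seq_along(motifs), function(i) {
      mis <- .windowMismatches(chars, motifs[i])
      cand <- which(mis <= maxMismatch)
      if (!length(cand)) return(NULL)
      best <- cand[which.min(mis[cand])]
      c(start = best, end = best + nchar(motifs[i]) - 1L)
    })
    hits[!vapply(hits, is.null, TRUE)]
  }
  frameHits <- lapply(trans, scanFrame)
  nHits <- vapply(frameHits, length, 0L)
  if (max(nHits) == 0L)
    stop("no-orf: no reading frame contains a Rab motif hit")
  frame <- which.max(nHits)
  hits <- frameHits[[frame]]
  firstMotifAA <- min(vapply(hits, `[[`, 0L, "start"))
  lastMotifAA <- max(vapply(hits, `[[`, 0L, "end"))
  ## protein position p (1-based, frame f) covers nucleotides
  ## f + 3*(p-1) .. f + 3*p - 1
  aaToNt <- function(p) frame + 3L * (p - 1L)
  n <- nchar(mrna)
  codonStarts <- seq.int(frame, n - 2L, by = 3L)
  codons <- substring(mrna, codonStarts, codonStarts + 2L)
  firstMotifNt <- aaToNt(firstMotifAA)
  atg <- codonStarts[codons == "ATG" & codonStarts <= firstMotifNt]
  atg <- atg[firstMotifNt - atg <= maxStartUpstream]
  if (!length(atg))
    stop("missing-start: no in-frame ATG at or upstream of the first motif")
  start <- max(atg)
  lastMotifNtEnd <- aaToNt(lastMotifAA) + 2L
  tga <- codonStarts[codons == "TGA" & codonStarts > lastMotifNtEnd]
  if (!length(tga))
    stop("missing-stop: no in-frame TGA downstream of the last motif")
  stopPos <- min(tga)
  cds <- substr(mrna, start, stopPos - 1L)
  peptide <- translateCiliate(cds, 1L, toFirstStop = TRUE)
  if (grepl("\\*", translateCiliate(cds, 1L, toFirstStop = FALSE)))
    stop("no-orf: in-frame TGA interrupts the motif-bearing reading frame")
  list(frame = frame, start = start, stop = stopPos, peptide = peptide)
}

#' Predict ORFs for a FASTA of transcripts
#'
#' @param x path to a nucleotide FASTA, a named character vector, or a
#'   \code{DNAStringSet}.
#' @inheritParams predictOrf
#' @param proteinFile,tableFile optional output paths for the predicted
#'   peptides (FASTA) and the frame/start/stop table (TSV, 1-based
#'   inclusive coordinates).
#' @return data.frame with columns id, frame, start, stop, peptide; rows
#'   for transcripts where no ORF was found carry NA and the error message
#'   in the \code{error} column.
#' @export
predictOrfSet <- function(x, library = defaultMotifLibrary(),
                          maxMismatch = 2L, proteinFile = NULL,
                          tableFile = NULL) {
  if (is.character(x) && length(x) == 1L && file.exists(x))
    x <- Biostrings::readDNAStringSet(x)
  if (methods::is(x, "DNAStringSet"))
    x <- setNames(as.character(x), names(x))
  rows <- lapply(names(x), function(id) {
    res <- tryCatch(predictOrf(x[[id]], library, maxMismatch),
                    error = function(e) conditionMessage(e))
    if (is.character(res))
      data.frame(id = id, frame = NA_integer_, start = NA_integer_,
                 stop = NA_integer_, peptide = NA_character_, error = res)
    else
      data.frame(id = id, frame = res$frame, start = res$start,
                 stop = res$stop, peptide = res$peptide,
                 error = NA_character_)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$frame)
  if (!is.null(proteinFile))
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(setNames(out$peptide[ok], out$id[ok])),
      proteinFile)
  if (!is.null(tableFile))
    write.table(out[, c("id", "frame", "start", "stop")], tableFile,
                sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
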