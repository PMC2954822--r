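## Independent oracles and small generators used across the suite. These are
## deliberately naive (loops, substring enumeration) so they share no code
## path with the implementation they check.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                   collapse = "")

## exhaustive window scan: mismatch count of `motif` at every start position
bruteWindowScan <- function(seq, motif) {
  n <- nchar(seq); k <- nchar(motif)
  if (n < k) return(data.frame(position = integer(), mismatches = integer()))
  mm <- vapply(seq_len(n - k + 1), function(p) {
    w <- substr(seq, p, p + k - 1)
    sum(utf8ToInt(w) != utf8ToInt(motif))
  }, 0L)
  data.frame(position = seq_len(n - k + 1), mismatches = mm)
}

## best window (fewest mismatches, leftmost) with at most maxMismatch
bruteBestWindow <- function(seq, motif, maxMismatch, minStart = 1) {
  sc <- bruteWindowScan(seq, motif)
  sc <- sc[sc$position >= minStart & sc$mismatches <= maxMismatch, ]
  if (!nrow(sc)) return(NULL)
  sc[which.min(sc$mismatches), ]
}

## random additive distance matrix: assign branch lengths to a random
## topology and sum path lengths
randomAdditiveMatrix <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   tip.label = sprintf("x%02d", seq_len(ntaxa)))
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

## a protein with the five RabF motifs planted in order plus a given tail
motifProtein <- function(tail = "SNCC", spacer = 10,
                         motifs = c("IGVDF", "KLQIW", "RFRSIT", "YYRGA",
                                    "LVYDIT")) {
  paste0("M", paste(vapply(motifs, function(m)
    paste0(m, strrep("A", spacer)), ""), collapse = ""), tail)
}
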