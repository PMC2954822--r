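## Alignment trimming, distance estimation, native neighbor joining with
## bootstrap support, majority-rule consensus, and the multi-method
## conserved / lineage-restricted / divergent classification.

## alignment -> character matrix (rows = sequences, cols = sites)
.alnMatrix <- function(aln) {
  if (methods::is(aln, "AAStringSet"))
    aln <- setNames(as.character(aln), names(aln))
  if (!is.character(aln) || is.null(names(aln)))
    stop("alignment must be a named character vector or AAStringSet")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows must all have equal length")
  if (!all(grepl("^[ACDEFGHIKLMNPQRSTVWYX*-]*$", aln)))
    stop("alignment alphabet must be amino acids plus gap")
  do.call(rbind, strsplit(aln, ""))
}

.matrixToAln <- function(m) {
  Biostrings::AAStringSet(setNames(apply(m, 1L, paste, collapse = ""),
                                   rownames(m)))
}

#' Read a multiple alignment
#'
#' @param path file path.
#' @param format \code{"fasta"} (aligned FASTA) or \code{"phylip"}
#'   (relaxed sequential PHYLIP: a header line with the number of taxa and
#'   sites, then one \code{name sequence} line per taxon).
#' @return an \code{AAStringSet} of equal-width gapped sequences.
#' @export
readAlignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  if (format == "fasta") {
    aln <- Biostrings::readAAStringSet(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]])
    recs <- strsplit(trimws(lines[-1L]), "\\s+")
    if (length(recs) != hdr[1L])
      stop("phylip header announces ", hdr[1L], " taxa, found ", length(recs))
    aln <- Biostrings::AAStringSet(setNames(
      vapply(recs, function(r) paste(r[-1L], collapse = ""), ""),
      vapply(recs, `[[`, "", 1L)))
  }
  .alnMatrix(aln)  # validates
  aln
}

#' Trim an alignment for phylogenetic inference
#'
#' Removes the C-terminal hypervariable region and gap-bearing columns
#' before distance estimation. With \code{ctermTrim = "auto"} the cutoff is
#' the alignment column holding the end of the last RabF motif occurrence in
#' any sequence (found on the degapped sequences with the given mismatch
#' tolerance); everything after it is dropped, capped so no sequence loses
#' more than \code{maxTail} residues. A numeric \code{ctermTrim} masks that
#' many C-terminal residues of every sequence instead. Finally every column
#' containing at least one gap is removed (when \code{removeGapColumns}).
#'
#' @param aln named character vector or \code{AAStringSet} of equal-width
#'   gapped sequences.
#' @param ctermTrim \code{"auto"} or a single nonnegative residue count.
#' @param removeGapColumns drop columns containing any gap (default TRUE).
#' @param library,maxMismatch motif library and tolerance for auto mode.
#' @param maxTail cap on per-sequence residues removed in auto mode
#'   (default 80, the upper end of typical Rab hypervariable tails).
#' @param minColumns error if fewer columns remain (default 10).
#' @return trimmed alignment as an \code{AAStringSet}; never wider than the
#'   input.
#' @export
trimAlignment <- function(aln, ctermTrim = "auto", removeGapColumns = TRUE,
                          library = defaultMotifLibrary(), maxMismatch = 2L,
                          maxTail = 80L, minColumns = 10L) {
  m <- .alnMatrix(aln)
  nc <- ncol(m)
  if (identical(ctermTrim, "auto")) {
    ## per sequence: alignment column of the last residue of its last motif
    cut <- 0L
    resid <- integer(nrow(m))
    for (i in seq_len(nrow(m))) {
      nonGap <- which(m[i, ] != "-")
      seq_i <- paste(m[i, nonGap], collapse = "")
      hits <- scanRabMotifs(seq_i, library, maxMismatch)
      if (!nrow(hits)) next
      lastRes <- max(hits$position + nchar(hits$motif) - 1L)
      cut <- max(cut, nonGap[lastRes])
      resid[i] <- length(nonGap)
    }
    if (cut == 0L) cut <- nc  # no motifs anywhere: nothing to anchor on
    ## never remove more than maxTail residues from any one sequence
    repeat {
      lost <- vapply(seq_len(nrow(m)), function(i)
        sum(m[i, seq_len(nc) > cut] != "-"), 0L)
      if (all(lost <= maxTail) || cut >= nc) break
      cut <- cut + 1L
    }
    m <- m[, seq_len(cut), drop = FALSE]
  } else {
    k <- as.integer(ctermTrim)
    if (k < 0L) stop("`ctermTrim` must be \"auto\" or a nonnegative count")
    if (k > 0L)
      for (i in seq_len(nrow(m))) {
        nonGap <- which(m[i, ] != "-")
        if (k >= length(nonGap))
          stop("`ctermTrim` exceeds the length of sequence ", rownames(m)[i])
        m[i, utils::tail(nonGap, k)] <- "-"
      }
  }
  if (removeGapColumns) {
    keep <- colSums(m == "-") == 0L
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) < minColumns)
    stop("too short: trimming left ", ncol(m), " columns (< ", minColumns, ")")
  .matrixToAln(m)
}

#' Pairwise distances from a trimmed alignment
#'
#' p-distance is the fraction of mismatching residues over sites where both
#' sequences have a residue (pairwise deletion of gaps); the Poisson
#' correction is \code{-ln(1 - p)}.
#'
#' @inheritParams trimAlignment
#' @param model \code{"p"} or \code{"poisson"}.
#' @return symmetric numeric matrix with zero diagonal and the sequence ids
#'   as dimnames; the model is recorded in the \code{"model"} attribute.
#' @export
computeDistances <- function(aln, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- .alnMatrix(aln)
  if (nrow(m) < 3L) stop("need at least 3 sequences")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("no comparable sites between ",
                         rownames(m)[i], " and ", rownames(m)[j])
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      if (model == "poisson") {
        if (p >= 1) stop("infinite distance: p >= 1 under the Poisson model")
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  attr(D, "model") <- model
  D
}

#' Neighbor-joining tree reconstruction
#'
#' Standard Saitou-Nei agglomeration with the Q-matrix criterion. Ties for
#' the minimum Q are broken deterministically by the lexicographically
#' smallest id pair (clusters are ranked by their smallest member id).
#' Negative branch-length estimates are clamped to 0. The result is exact
#' on additive distance matrices.
#'
#' @param D symmetric nonnegative distance matrix with unique dimnames and
#'   zero diagonal.
#' @return an unrooted \code{ape::phylo} tree.
#' @export
neighborJoining <- function(D) {
  if (!is.matrix(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("`D` must be a symmetric matrix")
  if (any(D < 0)) stop("`D` must be nonnegative")
  ids <- rownames(D)
  if (is.null(ids) || anyDuplicated(ids)) stop("`D` needs unique dimnames")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  ## each active cluster: newick fragment + representative (smallest leaf id)
  frag <- ids
  rep_ <- ids
  fmt <- function(x) sprintf("%.10g", max(x, 0))
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(rep_[ij[1L]], rep_[ij[2L]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(bi), frag[j], fmt(bj))
    newRep <- min(rep_[i], rep_[j])
    dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
               c(dNew[keep], 0))
    frag <- c(frag[keep], newFrag)
    rep_ <- c(rep_[keep], newRep)
    rownames(D) <- colnames(D) <- rep_
    n <- n - 1L
  }
  ## final three-point join
  x1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  x2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  x3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], fmt(x1), frag[2], fmt(x2), frag[3], fmt(x3))
  ape::read.tree(text = nwk)
}

## canonical key for the bipartition induced by a clade: the side not
## containing the alphabetically first leaf, sorted
.splitKey <- function(members, allLeaves) {
  ref <- min(allLeaves)
  side <- if (ref %in% members) setdiff(allLeaves, members) else members
  paste(sort(side), collapse = "\r")
}

## non-trivial bipartition keys of a tree (sides of size 2..n-2)
.treeSplits <- function(tree) {
  leaves <- tree$tip.label
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (cl in pp) {
    mem <- attr(pp, "labels")[cl]
    sz <- length(mem)
    if (sz < 2L || sz > length(leaves) - 2L) next
    keys <- c(keys, .splitKey(mem, leaves))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement (\code{nReps} replicates),
#' rebuilds the NJ tree for each replicate, and maps bipartition
#' frequencies, as percentages, onto the full-data NJ tree (supports are
#' attached to the full-data tree, not to a consensus). Identical seeds
#' give identical output.
#'
#' @inheritParams computeDistances
#' @param nReps number of bootstrap replicates (default 100).
#' @param seed integer RNG seed for the column resampling.
#' @return the full-data NJ tree with internal \code{node.label} support
#'   percentages in [0, 100] (the root label is empty). The seed and
#'   replicate count are recorded in attributes \code{"seed"} and
#'   \code{"nReps"}.
#' @export
bootstrapSupport <- function(aln, model = c("p", "poisson"), nReps = 100L,
                             seed = 1L) {
  model <- match.arg(model)
  if (nReps < 1L) stop("`nReps` must be >= 1")
  m <- .alnMatrix(aln)
  full <- neighborJoining(computeDistances(.matrixToAln(m), model))
  leaves <- full$tip.label
  counts <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  for (b in seq_len(nReps)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    bt <- tryCatch(
      neighborJoining(computeDistances(.matrixToAln(m[, cols, drop = FALSE]),
                                       model)),
      error = function(e) NULL)
    if (is.null(bt)) next
    for (k in .treeSplits(bt))
      assign(k, (if (exists(k, counts)) get(k, counts) else 0L) + 1L, counts)
  }
  pp <- ape::prop.part(full)
  labs <- character(full$Nnode)
  for (nd in seq_len(full$Nnode)) {
    mem <- attr(pp, "labels")[pp[[nd]]]
    if (length(mem) < 2L || length(mem) > length(leaves) - 2L) next
    k <- .splitKey(mem, leaves)
    cnt <- if (exists(k, counts)) get(k, counts) else 0L
    labs[nd] <- sprintf("%g", 100 * cnt / nReps)
  }
  full$node.label <- labs
  attr(full, "seed") <- seed
  attr(full, "nReps") <- nReps
  full
}

#' Majority-rule consensus of trees on the same leaf set
#'
#' Bipartitions present in strictly more than half of the input trees are
#' retained; each retained internal node is labeled with its occurrence
#' percentage. Incompatible minority splits are collapsed (a fully
#' unresolved quartet set yields a star tree).
#'
#' @param trees list of \code{ape::phylo} trees with identical leaf sets.
#' @return an \code{ape::phylo} consensus tree with support percentages as
#'   \code{node.label}.
#' @export
majorityConsensus <- function(trees) {
  if (length(trees) < 2L) stop("need at least 2 trees")
  leaves <- sort(trees[[1L]]$tip.label)
  for (t in trees)
    if (!identical(sort(t$tip.label), leaves))
      stop("trees must share an identical leaf set")
  nT <- length(trees)
  allKeys <- unlist(lapply(trees, .treeSplits))
  tab <- table(allKeys)
  kept <- names(tab)[tab / nT > 0.5]
  support <- 100 * as.numeric(tab[kept]) / nT
  ## majority splits are pairwise compatible; build a rooted nesting with the
  ## alphabetically first leaf as the outside reference, then read as newick
  ref <- min(leaves)
  clusters <- lapply(kept, function(k) strsplit(k, "\r", fixed = TRUE)[[1L]])
  inner <- setdiff(leaves, ref)
  ord <- order(vapply(clusters, length, 0L), decreasing = TRUE)
  clusters <- clusters[ord]
  support <- support[ord]
  nest <- function(set, avail) {
    isMax <- vapply(seq_along(avail$cl), function(i) {
      ci <- avail$cl[[i]]
      !any(vapply(seq_along(avail$cl), function(j)
        j != i && all(ci %in% avail$cl[[j]]), TRUE))
    }, TRUE)
    parts <- character(0)
    covered <- character(0)
    for (i in which(isMax)) {
      ci <- avail$cl[[i]]
      sub <- list(cl = list(), sup = numeric(0))
      for (j in seq_along(avail$cl))
        if (j != i && all(avail$cl[[j]] %in% ci)) {
          sub$cl <- c(sub$cl, avail$cl[j])
          sub$sup <- c(sub$sup, avail$sup[j])
        }
      parts <- c(parts,
                 sprintf("(%s)%g", nest(ci, sub), avail$sup[i]))
      covered <- c(covered, ci)
    }
    parts <- c(parts, setdiff(set, covered))
    paste(parts, collapse = ",")
  }
  nwk <- sprintf("(%s,%s);", ref,
                 nest(inner, list(cl = clusters, sup = support)))
  ape::read.tree(text = nwk)
}

## clades (leaf-id vectors) of a tree's internal nodes with numeric supports;
## unlabeled nodes are treated as fully supported
.supportedClades <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- tree$node.label
  n <- length(tree$tip.label)
  out <- list()
  for (nd in seq_along(pp)) {
    mem <- attr(pp, "labels")[pp[[nd]]]
    if (length(mem) < 2L || length(mem) >= n) next
    sup <- if (is.null(labs) || nd > length(labs) || is.na(labs[nd]) ||
               !nzchar(labs[nd])) 100 else suppressWarnings(as.numeric(labs[nd]))
    if (is.na(sup)) sup <- 100
    out[[length(out) + 1L]] <- list(members = mem, support = sup)
  }
  out
}

#' Classify queries as conserved, lineage-restricted, or divergent
#'
#' Operationalizes the multi-method conservation call: for each query and
#' each tree, the smallest clade with support at or above
#' \code{supportThreshold} containing the query plus at least one other
#' leaf is located. A query is \emph{conserved} when, in at least
#' \code{conservedQuorum} trees, that clade contains a non-ciliate
#' reference; \emph{lineage-restricted} when in \emph{all} trees the clade
#' exists and contains only ciliate-tagged leaves; \emph{divergent}
#' otherwise (e.g. no supported clade in any method).
#'
#' @param queryIds character vector of query leaf ids.
#' @param trees list of \code{ape::phylo} trees (one per tree-building
#'   method), each containing every query; internal \code{node.label}s are
#'   read as support percentages (unlabeled nodes count as supported).
#' @param lineageMap named character vector mapping every leaf id to a
#'   lineage tag.
#' @param supportThreshold minimum support percentage (default 50, the
#'   display threshold used for published bootstrap figures).
#' @param conservedQuorum trees required for a conserved call (default 2,
#'   the "2 of 3 methods" rule).
#' @param ciliateTag lineage tag marking ciliate leaves (default
#'   \code{"ciliate"}).
#' @return data.frame with columns \code{query}, \code{status},
#'   \code{supporting_methods}; per-tree clade membership is attached as
#'   the \code{"clades"} attribute (a list indexed by query).
#' @export
classifyConservation <- function(queryIds, trees, lineageMap,
                                 supportThreshold = 50, conservedQuorum = 2L,
                                 ciliateTag = "ciliate") {
  if (!length(trees)) stop("empty tree list")
  for (t in trees) {
    miss <- setdiff(queryIds, t$tip.label)
    if (length(miss))
      stop("query absent from a tree: ", paste(miss, collapse = ", "))
    unmapped <- setdiff(t$tip.label, names(lineageMap))
    if (length(unmapped))
      stop("lineageMap must cover every leaf; missing: ",
           paste(unmapped, collapse = ", "))
  }
  cladeSets <- lapply(trees, .supportedClades)
  cladeInfo <- list()
  rows <- lapply(queryIds, function(q) {
    perTree <- lapply(cladeSets, function(cls) {
      cls <- Filter(function(cl) cl$support >= supportThreshold &&
                      q %in% cl$members, cls)
      if (!length(cls)) return(NULL)
      cls[[which.min(vapply(cls, function(cl) length(cl$members), 0L))]]
    })
    hasClade <- !vapply(perTree, is.null, TRUE)
    withNonCiliate <- vapply(seq_along(perTree), function(i) {
      cl <- perTree[[i]]
      !is.null(cl) &&
        any(lineageMap[setdiff(cl$members, q)] != ciliateTag)
    }, TRUE)
    ciliateOnly <- vapply(seq_along(perTree), function(i) {
      cl <- perTree[[i]]
      !is.null(cl) && all(lineageMap[cl$members] == ciliateTag)
    }, TRUE)
    if (sum(withNonCiliate) >= conservedQuorum) {
      status <- "conserved"; nsup <- sum(withNonCiliate)
    } else if (all(ciliateOnly)) {
      status <- "lineage-restricted"; nsup <- length(trees)
    } else {
      status <- "divergent"; nsup <- sum(hasClade)
    }
    cladeInfo[[q]] <<- lapply(perTree, function(cl)
      if (is.null(cl)) character(0) else sort(cl$members))
    data.frame(query = q, status = status, supporting_methods = nsup)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "clades") <- cladeInfo
  out
}

#' Write / read a distance matrix as square TSV
#'
#' @param D matrix as produced by \code{\link{computeDistances}}.
#' @param path file path.
#' @return \code{readDistanceMatrix} returns the matrix.
#' @export
writeDistanceMatrix <- function(D, path) {
  write.table(D, path, sep = "\t", quote = FALSE, col.names = NA)
}

#' @rdname writeDistanceMatrix
#' @export
readDistanceMatrix <- function(path) {
  df <- read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}
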