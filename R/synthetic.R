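## Seeded generators producing inputs with the structure the analysis
## modules assume, each a pure function of (seed, parameters) and each
## carrying its ground truth ("SimTruth") for closure tests.

## evaluate expr under a fixed seed without disturbing the caller's RNG
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  expr
}

.sampleAA <- function(n, exclude = character(0)) {
  pool <- setdiff(.AA_ALPHABET, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

## reverse ciliate codon table: amino acid -> codons (TGA excluded, it is
## the sole stop)
.ciliateCodonsByAA <- function() {
  code <- ciliateGeneticCode()
  code <- code[code != "*"]
  split(names(code), unname(code))
}

#' Simulate a small-GTPase coding gene with known class
#'
#' Builds a protein with the five RabF motifs planted in order (mutated as
#' requested) and a C terminus dictated by the class label: a prenylation
#' motif for \code{"Rab"}, a cysteine-free tail for \code{"Rab-like"}. For
#' \code{"non-Rab"} the Ras consensus motifs are planted instead. The
#' protein is back-translated under the ciliate nuclear code with uniform
#' choice among synonymous codons, flanked by random UTRs, and terminated
#' by an in-frame TGA, so ORF prediction can be scored against the planted
#' frame/start/stop. Spacer regions avoid methionine so the planted start
#' codon is the nearest in-frame ATG upstream of the first motif.
#'
#' @param seed integer seed; identical seeds give identical output.
#' @param classLabel \code{"Rab"}, \code{"Rab-like"} or \code{"non-Rab"}.
#' @param mutationsPerMotif substitutions introduced into each planted
#'   motif (default 0).
#' @param tailPattern for class \code{"Rab"}, one of CC, CXC, CCX, CCXX,
#'   CXXX (default: drawn at random).
#' @param library a \linkS4class{MotifLibrary}.
#' @return list with \code{protein}, \code{mrna}, and \code{truth} (class
#'   label, frame, start, stop, motif positions, tail pattern, seed).
#' @export
simulateRabGene <- function(seed, classLabel = c("Rab", "Rab-like", "non-Rab"),
                            mutationsPerMotif = 0L, tailPattern = NULL,
                            library = defaultMotifLibrary()) {
  classLabel <- match.arg(classLabel)
  .withSeed(seed, {
    motifs <- if (classLabel == "non-Rab") familyMotifs(library)[["Ras"]]
      else rabMotifs(library)
    ## mutate motifs
    planted <- vapply(motifs, function(m) {
      if (mutationsPerMotif == 0L) return(m)
      ch <- strsplit(m, "")[[1L]]
      pos <- sample(length(ch), min(mutationsPerMotif, length(ch)))
      for (p in pos)
        ch[p] <- sample(setdiff(.AA_ALPHABET, c(ch[p], "M", "C")), 1L)
      paste(ch, collapse = "")
    }, "", USE.NAMES = FALSE)
    ## spacers avoid M (start-codon bookkeeping) and C (prenylation is
    ## controlled solely by the constructed tail)
    sp <- function(n) .sampleAA(n, exclude = c("M", "C"))
    tail4 <- switch(classLabel,
      "Rab" = {
        if (is.null(tailPattern))
          tailPattern <- sample(c("CC", "CXC", "CCX", "CCXX", "CXXX"), 1L)
        x <- function() sample(setdiff(.AA_ALPHABET, "C"), 1L)
        switch(tailPattern,
          CC = paste0(x(), x(), "CC"),
          CXC = paste0(x(), "C", x(), "C"),
          CCX = paste0(x(), "CC", x()),
          CCXX = paste0("CC", x(), x()),
          CXXX = paste0("C", x(), x(), x()),
          stop("unknown tail pattern: ", tailPattern))
      },
      "Rab-like" = { tailPattern <- "none"; sp(4L) },
      "non-Rab" = {
        if (is.null(tailPattern)) tailPattern <- "none"
        sp(4L)
      })
    segs <- character(0)
    motifStartsAA <- integer(length(planted))
    cur <- 1L  # "M"
    segs <- "M"
    cur <- cur + 1L
    for (i in seq_along(planted)) {
      gap <- sp(sample(8:14, 1L))
      segs <- c(segs, gap)
      cur <- cur + nchar(gap)
      motifStartsAA[i] <- cur
      segs <- c(segs, planted[i])
      cur <- cur + nchar(planted[i])
    }
    hyp <- sp(sample(18:30, 1L))  # C-terminal hypervariable tail
    segs <- c(segs, hyp, tail4)
    protein <- paste(segs, collapse = "")
    ## back-translate under the ciliate code
    codons <- .ciliateCodonsByAA()
    cds <- vapply(strsplit(protein, "")[[1L]], function(aa) {
      cc <- codons[[aa]]
      cc[sample.int(length(cc), 1L)]
    }, "", USE.NAMES = FALSE)
    cds <- paste(cds, collapse = "")
    utr5 <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1L),
                         replace = TRUE), collapse = "")
    utr3 <- paste(sample(c("A", "C", "G", "T"), sample(30:60, 1L),
                         replace = TRUE), collapse = "")
    start <- nchar(utr5) + 1L
    stopPos <- start + nchar(cds)
    mrna <- paste0(utr5, cds, "TGA", utr3)
    list(
      protein = protein,
      mrna = mrna,
      truth = list(class = classLabel, frame = ((start - 1L) %% 3L) + 1L,
                   start = start, stop = stopPos,
                   motif_starts_aa = motifStartsAA,
                   tail_pattern = tailPattern, seed = seed,
                   mutations_per_motif = mutationsPerMotif)
    )
  })
}

#' Evolve a protein family along a known tree
#'
#' A random root sequence is evolved along the tree by independent-site
#' substitution: the number of events per site on a branch is Poisson with
#' mean rate x branch length, and each event replaces the residue with one
#' of the other 19 drawn uniformly (a Jukes-Cantor-like model on amino
#' acids, chosen for its analytic transparency rather than realism). The
#' result is a gapless alignment.
#'
#' @param tree an \code{ape::phylo} tree with positive branch lengths and
#'   at least one leaf.
#' @param rate expected substitutions per site per unit branch length.
#' @param seed integer seed.
#' @param rootLength root sequence length in residues (default 150).
#' @return list with \code{alignment} (an \code{AAStringSet}, one gapless
#'   row per leaf) and \code{truth} (tree, root sequence, rate, seed).
#' @export
simulateFamily <- function(tree, rate, seed, rootLength = 150L) {
  if (is.null(tree$tip.label) || !length(tree$tip.label))
    stop("tree has no leaves")
  .withSeed(seed, {
    rootSeq <- sample(.AA_ALPHABET, rootLength, replace = TRUE)
    ntip <- length(tree$tip.label)
    rootNode <- ntip + 1L
    seqs <- vector("list", ntip + tree$Nnode)
    seqs[[rootNode]] <- rootSeq
    ## preorder traversal: parents always precede children in the edge list
    ## after reorder()
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      len <- tr$edge.length[e]
      s <- seqs[[parent]]
      nSub <- rpois(length(s), rate * len)
      for (i in which(nSub > 0L))
        for (k in seq_len(nSub[i]))
          s[i] <- sample(setdiff(.AA_ALPHABET, s[i]), 1L)
      seqs[[child]] <- s
    }
    aln <- Biostrings::AAStringSet(setNames(
      vapply(seq_len(ntip), function(i) paste(seqs[[i]], collapse = ""), ""),
      tree$tip.label))
    list(alignment = aln,
         truth = list(tree = tree, root = paste(rootSeq, collapse = ""),
                      rate = rate, seed = seed))
  })
}

#' Simulate a stage-grid expression cohort with planted peaks
#'
#' Each gene gets a constant baseline over the 20-stage grid; planted peaks
#' multiply a single stage by the requested fold. Multiplicative log-normal
#' noise with the given coefficient of variation is applied to every value
#' (mean-preserving).
#'
#' @param nGenes number of genes.
#' @param plantedPeaks NULL, or a data.frame with columns \code{gene}
#'   (index in 1..nGenes), \code{stage} (a stage label) and \code{fold}
#'   (> 1).
#' @param noiseCv coefficient of variation of the multiplicative noise
#'   (default 0).
#' @param seed integer seed.
#' @param baseline mean baseline intensity in arbitrary units
#'   (default 1000).
#' @param file optional TSV output path.
#' @return list with \code{expr} (a \linkS4class{StageExpressionSet}) and
#'   \code{truth} (the planted peak table, baselines, CV, seed).
#' @export
simulateExpression <- function(nGenes, plantedPeaks = NULL, noiseCv = 0,
                               seed = 1L, baseline = 1000, file = NULL) {
  ss <- stageSet()
  if (!is.null(plantedPeaks)) {
    bad <- setdiff(plantedPeaks$stage, ss$stage)
    if (length(bad))
      stop("invalid stage label in planted peaks: ", paste(bad, collapse = ", "))
    if (any(plantedPeaks$fold <= 1)) stop("peak folds must be > 1")
  }
  .withSeed(seed, {
    base <- baseline * exp(rnorm(nGenes, 0, 0.25))
    mat <- matrix(rep(base, each = nrow(ss)), nrow = nGenes, byrow = TRUE,
                  dimnames = list(sprintf("gene%03d", seq_len(nGenes)),
                                  ss$stage))
    if (!is.null(plantedPeaks))
      for (k in seq_len(nrow(plantedPeaks))) {
        g <- plantedPeaks$gene[k]
        mat[g, plantedPeaks$stage[k]] <-
          mat[g, plantedPeaks$stage[k]] * plantedPeaks$fold[k]
      }
    if (noiseCv > 0) {
      sdlog <- sqrt(log(1 + noiseCv^2))
      noise <- matrix(rlnorm(length(mat), -sdlog^2 / 2, sdlog), nrow(mat))
      mat <- mat * noise
    }
    expr <- StageExpressionSet(mat)
    if (!is.null(file)) writeExpression(expr, file)
    list(expr = expr,
         truth = list(planted_peaks = plantedPeaks, baselines = base,
                      noise_cv = noiseCv, seed = seed))
  })
}

#' Simulate a two-channel punctum image pair with known colocalization
#'
#' Gaussian puncta of unit amplitude are placed on a separation lattice so
#' puncta never overlap; a \code{colocFraction} share of the green puncta
#' share centers with red puncta, the rest are disjoint between channels.
#' Optional additive Gaussian noise is clipped at zero.
#'
#' @param shape integer(2), image dimensions (default 96 x 96).
#' @param nGreen,nRed puncta per channel.
#' @param colocFraction fraction of green puncta sharing a red center, in
#'   [0, 1].
#' @param psfSigma Gaussian sigma in pixels (default 1.5).
#' @param noiseSd additive Gaussian noise sd (default 0).
#' @param seed integer seed.
#' @return list with \code{green}, \code{red} (intensity matrices) and
#'   \code{truth} (planted fraction, punctum centers, parameters).
#' @export
simulateColocImage <- function(shape = c(96L, 96L), nGreen = 12L, nRed = 12L,
                               colocFraction = 0.5, psfSigma = 1.5,
                               noiseSd = 0, seed = 1L) {
  if (colocFraction < 0 || colocFraction > 1)
    stop("`colocFraction` must be in [0, 1]")
  spacing <- max(ceiling(6 * psfSigma), 4L)
  gx <- seq(spacing, shape[1L] - spacing, by = spacing)
  gy <- seq(spacing, shape[2L] - spacing, by = spacing)
  lattice <- expand.grid(x = gx, y = gy)
  nShared <- round(colocFraction * nGreen)
  nNeeded <- nShared + (nGreen - nShared) + nRed - nShared
  if (nNeeded > nrow(lattice))
    stop("more puncta than available well-separated positions")
  .withSeed(seed, {
    pick <- lattice[sample.int(nrow(lattice), nNeeded), , drop = FALSE]
    shared <- pick[seq_len(nShared), , drop = FALSE]
    gOnly <- pick[nShared + seq_len(nGreen - nShared), , drop = FALSE]
    rOnly <- pick[nGreen + seq_len(nRed - nShared), , drop = FALSE]
    render <- function(centers) {
      img <- matrix(0, shape[1L], shape[2L])
      if (!nrow(centers)) return(img)
      xs <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
      ys <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
      for (k in seq_len(nrow(centers)))
        img <- img + exp(-((xs - centers$x[k])^2 + (ys - centers$y[k])^2) /
                           (2 * psfSigma^2))
      img
    }
    green <- render(rbind(shared, gOnly))
    red <- render(rbind(shared, rOnly))
    if (noiseSd > 0) {
      green <- pmax(green + matrix(rnorm(length(green), 0, noiseSd),
                                   nrow(green)), 0)
      red <- pmax(red + matrix(rnorm(length(red), 0, noiseSd), nrow(red)), 0)
    }
    list(green = green, red = red,
         truth = list(coloc_fraction = colocFraction,
                      shared_centers = shared, green_only = gOnly,
                      red_only = rOnly, psf_sigma = psfSigma,
                      noise_sd = noiseSd, seed = seed))
  })
}
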