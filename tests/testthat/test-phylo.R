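test_that("trimming removes gap columns and is idempotent", {
  aln <- c(a = "MKLV-DEAGRTWYE", b = "MKLVADEAGRTWYE", c = "MKLVADEAGRTWYE")
  tr <- trimAlignment(aln, ctermTrim = 0)
  expect_equal(Biostrings::width(tr)[1], 13L)  # exactly the gap column lost
  ## gapless alignment with no trim is untouched
  aln2 <- c(a = "MKLVADEAGRTWYE", b = "MKLVADEAGRTWYE", c = "MKLVWDEAGRTWYE")
  expect_identical(as.character(trimAlignment(aln2, ctermTrim = 0)), aln2)
  ## idempotence of auto mode on a motif-bearing family
  fam <- lapply(1:4, function(i) paste0(motifProtein("AKSQ"),
                                        strrep("QNSTV", 8)))
  names(fam) <- paste0("r", 1:4)
  fam <- unlist(fam)
  t1 <- as.character(trimAlignment(fam))
  t2 <- as.character(trimAlignment(t1))
  expect_identical(t1, t2)
})

test_that("auto trim removes planted hypervariable tails", {
  ## 40-residue random tails after the last motif
  set.seed(13)
  core <- motifProtein("")
  rows <- setNames(vapply(1:5, function(i) paste0(core, randomProtein(40)), ""),
                   paste0("r", 1:5))
  tr <- trimAlignment(rows)
  expect_lte(Biostrings::width(tr)[1], nchar(core))
  expect_error(trimAlignment(rows, ctermTrim = nchar(rows[1]) - 5),
               "too short|exceeds")
})

test_that("p and Poisson distances match hand counts and closed forms", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAACC", c = "AAAAAAAAAA")
  D <- computeDistances(aln, "p")
  expect_equal(D["a", "b"], 0.2)
  expect_equal(D["a", "c"], 0)
  expect_true(isSymmetric(unname(D)))
  Dp <- computeDistances(aln, "poisson")
  expect_equal(Dp["a", "b"], -log(0.8))
  ## pairwise deletion of gaps
  alnG <- c(a = "AAAAA-AAAA", b = "AAAAACAAAC", c = "AAAAAAAAAA")
  Dg <- computeDistances(alnG, "p")
  expect_equal(Dg["a", "b"], 1 / 9)
  ## saturated pairs are rejected under poisson
  sat <- c(a = strrep("A", 12), b = strrep("C", 12), c = strrep("G", 12))
  expect_error(computeDistances(sat, "poisson"), "infinite")
})

test_that("three-taxon NJ solves the three-point formulas exactly", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighborJoining(D)
  expect_equal(ape::Ntip(tr), 3L)
  pd <- ape::cophenetic.phylo(tr)[rownames(D), colnames(D)]
  expect_equal(unname(pd), unname(D), tolerance = 1e-9)
})

test_that("NJ recovers additive matrices exactly (topology and lengths)", {
  set.seed(19)
  for (i in 1:30) {
    gen <- randomAdditiveMatrix(sample(4:12, 1))
    tr <- neighborJoining(gen$D)
    expect_equal(ape::dist.topo(ape::unroot(gen$tree), tr), 0,
                 ignore_attr = TRUE)
    pd <- ape::cophenetic.phylo(tr)[rownames(gen$D), colnames(gen$D)]
    expect_equal(pd, gen$D, tolerance = 1e-9)
    ## independent cross-check: agrees with ape's NJ topology
    expect_equal(ape::dist.topo(ape::nj(gen$D), tr), 0, ignore_attr = TRUE)
  }
})

test_that("NJ is deterministic on equidistant inputs and validates input", {
  ids <- c("a", "b", "c", "d")
  D <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  t1 <- ape::write.tree(neighborJoining(D))
  t2 <- ape::write.tree(neighborJoining(D))
  expect_identical(t1, t2)
  bad <- D; bad[1, 2] <- 5
  expect_error(neighborJoining(bad), "symmetric")
  expect_error(neighborJoining(D - 2), "nonnegative")
})

test_that("bootstrap supports are seeded, bounded and congruent-signal aware", {
  ## every column supports the same split: support must be 100
  aln <- c(t1 = strrep("AC", 10), t2 = strrep("AC", 10), t3 = strrep("AC", 10),
           t4 = strrep("GT", 10), t5 = strrep("GT", 10), t6 = strrep("GT", 10))
  bt <- bootstrapSupport(aln, "p", nReps = 100, seed = 9)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_true(any(sup == 100))
  ## byte-identical Newick under a fixed seed
  fam <- simulateFamily(ape::read.tree(
    text = "((x1:0.2,x2:0.2):0.1,(x3:0.2,x4:0.2):0.1);"), 1, 55,
    rootLength = 60)
  n1 <- ape::write.tree(bootstrapSupport(fam$alignment, "p", 50, seed = 3))
  n2 <- ape::write.tree(bootstrapSupport(fam$alignment, "p", 50, seed = 3))
  expect_identical(n1, n2)
  expect_error(bootstrapSupport(aln, "p", nReps = 0), ">= 1")
})

test_that("true bipartitions outscore false ones in simulation", {
  tree <- ape::read.tree(text = paste0(
    "(((t1:0.1,t2:0.1):0.05,(t3:0.1,t4:0.1):0.05):0.025,",
    "((t5:0.1,t6:0.1):0.05,(t7:0.1,t8:0.1):0.05):0.025);"))
  fam <- simulateFamily(tree, 1, 99, rootLength = 150)
  bt <- bootstrapSupport(fam$alignment, "p", nReps = 100, seed = 12)
  ## the full-data tree here matches the truth; its supports are high
  expect_equal(ape::dist.topo(ape::unroot(tree), bt), 0, ignore_attr = TRUE)
  sup <- suppressWarnings(as.numeric(bt$node.label))
  expect_gt(mean(sup[!is.na(sup)]), 60)
})

test_that("majority consensus keeps >50% splits with occurrence supports", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t3 <- ape::read.tree(text = "((a,c),(b,d));")
  same <- majorityConsensus(list(t1, t1, t1))
  expect_equal(ape::dist.topo(same, ape::unroot(t1)), 0, ignore_attr = TRUE)
  expect_true(all(suppressWarnings(
    as.numeric(same$node.label[nzchar(same$node.label)])) == 100))
  twoOfThree <- majorityConsensus(list(t1, t1, t3))
  sup <- suppressWarnings(as.numeric(
    twoOfThree$node.label[nzchar(twoOfThree$node.label)]))
  expect_equal(sup, 200 / 3, tolerance = 1e-4)
  ## three pairwise-incompatible quartet resolutions give a star
  t2 <- ape::read.tree(text = "((a,d),(b,c));")
  star <- majorityConsensus(list(t1, t2, t3))
  expect_equal(star$Nnode, 1L)
  expect_error(majorityConsensus(list(t1)), "at least 2")
  expect_error(majorityConsensus(list(
    t1, ape::read.tree(text = "((a,b),(c,e));"))), "identical leaf set")
})

test_that("conservation classification follows the quorum rules", {
  lin <- c(q = "ciliate", hs = "animal", pt = "ciliate", dd = "amoebozoan",
           at = "plant")
  conservedTree <- ape::read.tree(text = "((q:1,hs:1)90:1,(pt:1,(dd:1,at:1)70:1)80:1);")
  restrictedTree <- ape::read.tree(text = "((q:1,pt:1)95:1,(hs:1,(dd:1,at:1)70:1)80:1);")
  weakTree <- ape::read.tree(text = "((q:1,hs:1)30:1,(pt:1,(dd:1,at:1)20:1)10:1);")

  cons <- classifyConservation("q", list(conservedTree, conservedTree,
                                         restrictedTree), lin)
  expect_identical(cons$status, "conserved")
  expect_equal(cons$supporting_methods, 2L)

  restr <- classifyConservation("q", list(restrictedTree, restrictedTree,
                                          restrictedTree), lin)
  expect_identical(restr$status, "lineage-restricted")

  div <- classifyConservation("q", list(weakTree, weakTree, weakTree), lin)
  expect_identical(div$status, "divergent")

  ## mixed signal without quorum: one conserved tree out of three
  mix <- classifyConservation("q", list(conservedTree, restrictedTree,
                                        restrictedTree), lin)
  expect_identical(mix$status, "divergent")

  expect_error(classifyConservation("zz", list(conservedTree), lin), "absent")
  expect_error(classifyConservation("q", list(), lin), "empty")
})

test_that("classification is invariant to leaf-order and tree-order permutation", {
  lin <- c(q = "ciliate", hs = "animal", pt = "ciliate", dd = "amoebozoan")
  tA <- ape::read.tree(text = "((q:1,hs:1)90:1,(pt:1,dd:1)80:1);")
  tB <- ape::read.tree(text = "((pt:1,dd:1)80:1,(hs:1,q:1)90:1);")
  tC <- ape::read.tree(text = "((q:1,pt:1)90:1,(hs:1,dd:1)80:1);")
  r1 <- classifyConservation("q", list(tA, tA, tC), lin)
  r2 <- classifyConservation("q", list(tC, tB, tB), lin)
  expect_identical(r1$status, r2$status)
})

test_that("trees and distance matrices round-trip through files", {
  gen <- randomAdditiveMatrix(6)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceMatrix(gen$D, tsv)
  back <- readDistanceMatrix(tsv)
  expect_equal(back, gen$D, tolerance = 1e-9)
  ## newick round-trip preserves topology, lengths and supports
  fam <- simulateFamily(gen$tree, 0.5, 3, rootLength = 60)
  bt <- bootstrapSupport(fam$alignment, "p", 25, seed = 2)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(bt, nwk)
  back2 <- ape::read.tree(nwk)
  expect_equal(ape::dist.topo(bt, back2), 0, ignore_attr = TRUE)
  expect_equal(back2$edge.length, bt$edge.length, tolerance = 1e-6)
  expect_identical(back2$node.label, bt$node.label)
})

test_that("relaxed PHYLIP alignments are read", {
  phy <- withr::local_tempfile(fileext = ".phy")
  writeLines(c(" 3 8", "seqA MKLVDEAG", "seqB MKLVDEAG", "seqC MKLVDEAC"),
             phy)
  aln <- readAlignment(phy, "phylip")
  expect_identical(names(aln), c("seqA", "seqB", "seqC"))
  expect_equal(unique(Biostrings::width(aln)), 8L)
})
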