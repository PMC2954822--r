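test_that("exact RabF motifs are found in order with zero mismatches", {
  seq <- paste0("M", "IGVDF", strrep("A", 10), "KLQIW", strrep("A", 10),
                "RFRSIT", strrep("A", 10), "YYRGA", strrep("A", 10),
                "LVYDIT", "SNCC")
  hits <- scanRabMotifs(seq, maxMismatch = 0)
  expect_equal(nrow(hits), 5L)
  expect_equal(hits$mismatches, rep(0L, 5))
  expect_equal(hits$score, rep(1, 5))
  expect_true(all(diff(hits$position) > 0))
})

test_that("motif scan returns nothing on featureless sequence", {
  expect_equal(nrow(scanRabMotifs(strrep("A", 20), maxMismatch = 3)), 0L)
})

test_that("degenerate motifs are located where exhaustive enumeration puts them", {
  seq <- sub("IGVDF", "IGVEF", motifProtein(), fixed = TRUE)
  hits <- scanRabMotifs(seq, maxMismatch = 1)
  f1 <- hits[hits$motif_index == 1, ]
  oracle <- bruteBestWindow(seq, "IGVDF", 1)
  expect_equal(f1$position, oracle$position)
  expect_equal(f1$mismatches, oracle$mismatches)
  expect_equal(f1$mismatches, 1L)
})

test_that("zero-mismatch scan equals exact substring search on random sequences", {
  set.seed(101)
  lib <- defaultMotifLibrary()
  for (i in 1:200) {
    seq <- randomProtein(80)
    hits <- scanRabMotifs(seq, lib, maxMismatch = 0, requireOrder = FALSE)
    for (k in seq_along(rabMotifs(lib))) {
      m <- rabMotifs(lib)[k]
      exact <- gregexpr(m, seq, fixed = TRUE)[[1]]
      exact <- if (exact[1] == -1) integer(0) else as.integer(exact)
      got <- hits$position[hits$motif_index == k]
      if (length(exact)) expect_equal(got, exact[1])
      else expect_length(got, 0)
    }
  }
})

test_that("motif scan rejects invalid input", {
  expect_error(scanRabMotifs(""), "empty")
  expect_error(scanRabMotifs("MIGVDF1"), "alphabet")
})

test_that("family scoring separates Rab from other small-GTPase classes", {
  rab <- motifProtein()
  fc <- classifyGtpaseFamily(rab)
  expect_identical(fc$family, "Rab")
  expect_gt(fc$margin, 0)
  ## scores agree with brute-force best-window counts
  lib <- defaultMotifLibrary()
  chars <- rab
  oracleScore <- sum(vapply(rabMotifs(lib), function(m) {
    sc <- bruteWindowScan(chars, m)
    nchar(m) - min(sc$mismatches)
  }, 0))
  expect_equal(unname(fc$perFamilyScore["Rab"]), oracleScore)
  ## Ras-consensus sequence is not a Rab
  rasSeq <- paste0("M", paste(vapply(familyMotifs(lib)$Ras, function(m)
    paste0(m, strrep("L", 9)), ""), collapse = ""), "GSHV")
  expect_identical(classifyGtpaseFamily(rasSeq)$family, "Ras")
  expect_identical(callRabStatus(rasSeq)$status, "non-Rab")
})

test_that("low-information and tied sequences are called unknown", {
  expect_identical(classifyGtpaseFamily(strrep("A", 60))$family, "unknown")
  ## symmetric construction: equal best scores for Rab and Ras force a tie
  lib <- defaultMotifLibrary()
  sym <- paste0(paste(rabMotifs(lib), collapse = strrep("G", 4)),
                strrep("G", 4),
                paste(familyMotifs(lib)$Ras, collapse = strrep("G", 4)))
  ## Rab and Ras motif sets both total 27 residues, all planted exactly
  fc <- classifyGtpaseFamily(sym)
  expect_identical(fc$family, "unknown")
  expect_true(fc$tie)
})

test_that("prenylation patterns are matched at the C terminus in priority order", {
  cases <- list(c("MKGSNCC", "CC"), c("MKGSCAC", "CXC"), c("MKGSCCA", "CCX"),
                c("MKGCCAA", "CCXX"), c("MKGCVLL", "CXXX"),
                c("MKGAKSQ", "none"))
  for (cs in cases) {
    pc <- classifyPrenylation(cs[1])
    expect_identical(pc$pattern, cs[2])
    expect_identical(pc$prenylatable, cs[2] != "none")
  }
  expect_error(classifyPrenylation("CC"), "too short")
})

test_that("prenylation is blind to edits outside the last four residues", {
  set.seed(7)
  for (i in 1:25) {
    body <- randomProtein(30)
    tail <- substr(randomProtein(4), 1, 4)
    p1 <- classifyPrenylation(paste0(body, tail))
    p2 <- classifyPrenylation(paste0(randomProtein(55), tail))
    expect_identical(p1, p2)
  }
})

test_that("Rab status combines family, motif count and prenylation", {
  expect_identical(callRabStatus(motifProtein("SNCC"))$status, "Rab")
  expect_identical(callRabStatus(motifProtein("AKSQ"))$status, "Rab-like")
  expect_identical(callRabStatus(strrep("A", 80))$status, "non-Rab")
})

test_that("planted labels are recovered from simulated proteins", {
  labels <- rep(c("Rab", "Rab-like", "non-Rab"), each = 15)
  got <- vapply(seq_along(labels), function(i)
    callRabStatus(simulateRabGene(1000 + i, labels[i])$protein)$status, "")
  expect_identical(got, labels)
  ## with one substitution per motif, tolerance 2 still recovers >= 95%
  lab2 <- rep(c("Rab", "Rab-like"), each = 20)
  got2 <- vapply(seq_along(lab2), function(i)
    callRabStatus(simulateRabGene(2000 + i, lab2[i],
                                  mutationsPerMotif = 1)$protein,
                  maxMismatch = 2)$status, "")
  expect_gte(mean(got2 == lab2), 0.95)
})

test_that("diagnostic motif detection reports all exact occurrences", {
  seq <- paste0(strrep("A", 59), "WDIAGQE", strrep("G", 10), "WDIAGQE")
  expect_equal(detectDiagnosticMotif(seq), c(60L, 77L))
  expect_equal(detectDiagnosticMotif(strrep("A", 30)), integer(0))
  expect_error(detectDiagnosticMotif(seq, "NOPE"), "unknown")
})

test_that("annotateSequences produces the TSV report schema", {
  prots <- c(r1 = motifProtein("SNCC"), r2 = motifProtein("AKSQ"),
             r3 = strrep("L", 60))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  rep_ <- annotateSequences(prots, reportFile = tsv)
  expect_identical(rep_$status, c("Rab", "Rab-like", "non-Rab"))
  expect_identical(colnames(rep_),
                   c("id", "family", "n_motifs", "prenyl_pattern", "status"))
  back <- read.delim(tsv)
  expect_identical(back$status, rep_$status)
  expect_s3_class(attr(rep_, "hits"), "data.frame")
})

test_that("motif libraries round-trip through the plain-text config", {
  cfg <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# test library", "[Rab]", "IGVDF", "KLQIW", "RFRSIT",
               "YYRGA", "LVYDIT", "[Ras]", "GAGGVGK",
               "[diagnostic]", "WDIAGQE=WDIAGQE"), cfg)
  lib <- readMotifLibrary(cfg)
  expect_identical(rabMotifs(lib), rabMotifs(defaultMotifLibrary()))
  expect_identical(familyMotifs(lib), list(Ras = "GAGGVGK"))
  expect_error(defaultMotifLibrary(rab = c("IGVDF", "KLQIW")), "exactly 5")
})
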