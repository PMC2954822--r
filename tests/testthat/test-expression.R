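test_that("the stage grid is the fixed 20-stage three-condition layout", {
  ss <- stageSet()
  expect_equal(nrow(ss), 20L)
  expect_false(anyDuplicated(ss$stage) > 0)
  expect_equal(unname(table(ss$condition)[c("growth", "starvation",
                                            "conjugation")]),
               c(3L, 7L, 10L), ignore_attr = TRUE)
})

test_that("expression TSVs load, flag missing rows, and round-trip", {
  sim <- simulateExpression(3, seed = 21)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeExpression(sim$expr, tsv)
  back <- loadExpression(tsv)
  expect_equal(intensities(back), intensities(sim$expr), tolerance = 1e-12)
  ## a missing stage column is a structured error naming the column
  df <- read.delim(tsv, check.names = FALSE)
  df$C18 <- NULL
  tsv2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, tsv2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadExpression(tsv2), "C18")
  ## non-numeric cells are rejected; empty cells are flagged, not dropped
  df2 <- read.delim(tsv, check.names = FALSE)
  df2$S6[1] <- "oops"
  tsv3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(df2, tsv3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(loadExpression(tsv3), "non-numeric.*S6")
  df2$S6[1] <- NA
  write.table(df2, tsv3, sep = "\t", quote = FALSE, row.names = FALSE)
  flagged <- loadExpression(tsv3)
  expect_identical(flaggedGenes(flagged), rownames(intensities(flagged))[1])
})

test_that("expressed calls use a strict threshold within the condition", {
  prof <- setNames(rep(0, 20), stageSet()$stage)
  expect_false(callExpressed(prof, 10, "growth"))
  prof["S6"] <- 50
  expect_true(callExpressed(prof, 10, "starvation"))
  expect_false(callExpressed(prof, 10, "growth"))
  prof["Ll"] <- 10
  expect_false(callExpressed(prof, 10, "growth"))  # boundary: strict >
  expect_error(callExpressed(prof, 10, "mitosis"), "unknown condition")
  expect_error(callExpressed(prof, 0, "growth"), "> 0")
})

test_that("discrete peaks require strictly exceeding fold x best other stage", {
  flat <- setNames(rep(100, 20), stageSet()$stage)
  expect_equal(nrow(findDiscretePeaks(flat)), 0L)
  p <- flat; p["S6"] <- 500
  got <- findDiscretePeaks(p)
  expect_equal(got$stage, "S6")
  expect_equal(got$condition, "starvation")
  expect_equal(got$fold, 5)
  ## exactly 2.0-fold is not a peak
  p2 <- flat; p2["S6"] <- 200
  expect_equal(nrow(findDiscretePeaks(p2)), 0L)
  ## all-zero block yields no peak rather than an error
  zero <- setNames(rep(0, 20), stageSet()$stage)
  expect_equal(nrow(findDiscretePeaks(zero)), 0L)
  expect_error(findDiscretePeaks(flat, foldThreshold = 1), "> 1")
})

test_that("S0 is excluded by default but configurable", {
  prof <- setNames(rep(100, 20), stageSet()$stage)
  prof["S0"] <- 1000
  expect_equal(nrow(findDiscretePeaks(prof)), 0L)
  withS0 <- findDiscretePeaks(prof, excludeStages = character(0))
  expect_equal(withS0$stage, "S0")
})

test_that("peak calls are invariant to uniform profile rescaling", {
  set.seed(5)
  prof <- setNames(rlnorm(20, log(200), 0.1), stageSet()$stage)
  prof["C4"] <- prof["C4"] * 8
  p1 <- findDiscretePeaks(prof)
  p2 <- findDiscretePeaks(prof * 1e3)
  expect_identical(p1$stage, p2$stage)
  expect_equal(p1$fold, p2$fold, tolerance = 1e-12)
})

test_that("cohort summaries count expression, maxima and peak tallies", {
  ss <- stageSet()
  mat <- matrix(100, 4, 20, dimnames = list(paste0("g", 1:4), ss$stage))
  mat["g1", "S6"] <- 900   # starvation max + peak
  mat["g2", "S9"] <- 400   # starvation max + peak
  mat["g3", "C2"] <- 150   # conjugation max, no peak
  mat["g4", ] <- 0         # silent
  x <- StageExpressionSet(mat)
  sc <- summarizeCohort(x, backgroundThreshold = 10)
  expect_equal(unname(sc$fraction_expressed["growth"]), 0.75)
  expect_equal(unname(sc$fraction_max_in["starvation"]), 0.5)
  expect_equal(unname(sc$fraction_max_in["conjugation"]), 0.25)
  expect_equal(unname(sc$peak_tally["S6"]), 1L)
  expect_equal(unname(sc$peak_tally["S9"]), 1L)
  expect_equal(sum(sc$peak_tally), 2L)
  expect_error(summarizeCohort(StageExpressionSet(mat[0, , drop = FALSE])),
               "empty")
})

test_that("planted peaks are recovered noiselessly and tallied exactly", {
  peaks <- data.frame(gene = c(1, 2, 3), stage = c("S6", "C2", "C2"),
                      fold = c(5, 3, 4))
  sim <- simulateExpression(6, peaks, noiseCv = 0, seed = 77)
  sc <- summarizeCohort(sim$expr)
  expect_equal(unname(sc$peak_tally["S6"]), 1L)
  expect_equal(unname(sc$peak_tally["C2"]), 2L)
  expect_equal(sum(sc$peak_tally), 3L)
  got <- findDiscretePeaks(intensities(sim$expr)[1, ])
  expect_identical(got$stage, "S6")
  expect_equal(got$fold, 5, tolerance = 1e-9)
})
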