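test_that("generation is byte-identical under a fixed seed", {
  a <- simulateSnoRNAs(20, seed = 1)
  b <- simulateSnoRNAs(20, seed = 1)
  expect_identical(lapply(a, function(x) snoSeq(x@record)),
                   lapply(b, function(x) snoSeq(x@record)))
  expect_identical(lapply(a, function(x) x@truth$substrates),
                   lapply(b, function(x) x@truth$substrates))
  c <- simulateSnoRNAs(20, seed = 2)
  expect_false(identical(lapply(a, function(x) snoSeq(x@record)),
                         lapply(c, function(x) snoSeq(x@record))))
})

test_that("category mixes apportion by largest remainder", {
  expect_equal(unname(apportionCounts(c(a = 0.2, b = 0.8), 10)), c(2L, 8L))
  counts <- apportionCounts(c(CANONICAL = 2, FUNCTIONAL_NONCANONICAL = 6,
                              TANDEM_NO_STEM1 = 18, MISSING_SHEARED = 17,
                              NO_MOTIF = 0) / 43, 43)
  expect_equal(unname(counts), c(2L, 6L, 18L, 17L, 0L))
  expect_equal(sum(apportionCounts(rep(1 / 3, 3), 10)), 10L)
  expect_error(apportionCounts(c(0.5, 0.4), 10), "sum to 1")

  labeled <- simulateSnoRNAs(10, categoryMix = c(CANONICAL = 0.2,
                                                 TANDEM_NO_STEM1 = 0.8),
                             seed = 71)
  planted <- table(vapply(labeled, function(x) x@truth$category, character(1)))
  expect_equal(unname(planted[c("CANONICAL", "TANDEM_NO_STEM1")]),
               as.integer(c(2, 8)), ignore_attr = TRUE)
})

test_that("all-canonical mixes plant consensus windows", {
  labeled <- simulateSnoRNAs(8, categoryMix = c(CANONICAL = 1), seed = 72)
  for (lr in labeled) {
    tr <- lr@truth
    cwin <- substr(snoSeq(lr@record), tr$boxCprime[1], tr$boxCprime[2])
    dwin <- substr(snoSeq(lr@record), tr$boxDprime[1], tr$boxDprime[2])
    expect_match(cwin, "^[AG]UGAUGA$")
    expect_equal(dwin, "CUGA")
  }
})

test_that("planted features are self-consistent with re-derivation", {
  labeled <- simulateSnoRNAs(20, seed = 73)
  for (lr in labeled) {
    tr <- lr@truth
    if (is.null(tr$boxCprime)) next
    frame <- buildKTurnFrame(snoSeq(lr@record), tr$boxCprime[1],
                             tr$boxDprime[1], "internal")
    rederived <- evaluateFeatures(frame, snoSeq(lr@record))
    expect_equal(featureTable(rederived), featureTable(tr$features))
    expect_equal(classifyMotif(rederived)@category, tr$category)
  }
})

test_that("construct edits flip exactly the targeted features", {
  # a record with the 1b.1n pair but no 2b.2n pair and an intact stem I
  # (the native-construct situation)
  labeled <- simulateSnoRNAs(40, categoryMix = c(MISSING_SHEARED = 1),
                             seed = 74)
  kl1like <- Filter(function(lr) {
    f <- lr@truth$features
    f@hasSheared1 && !f@hasSheared2 && f@stem1Minus1
  }, labeled)
  expect_gt(length(kl1like), 0L)
  lr <- kl1like[[1]]
  frame <- buildKTurnFrame(snoSeq(lr@record), lr@truth$boxCprime[1],
                           lr@truth$boxDprime[1], "internal")
  pos <- framePositions(frame)

  # kl2 analogue: introducing the 2b.2n pair makes the motif functional
  kl2 <- applyConstructEdit(lr, "introduce_sheared2")
  expect_true(kl2@truth$features@hasSheared2)
  expect_equal(kl2@truth$category, "FUNCTIONAL_NONCANONICAL")
  diffs <- which(strsplit(snoSeq(kl2@record), "")[[1]] !=
                   strsplit(snoSeq(lr@record), "")[[1]])
  expect_true(all(diffs %in% pos[c("b2", "n2")]))
  # re-breaking the edited position restores the original sequence
  restored <- snoSeq(kl2@record)
  for (d in diffs)
    substr(restored, d, d) <- substr(snoSeq(lr@record), d, d)
  expect_identical(restored, snoSeq(lr@record))

  # kl3 analogue: stem I to loop
  kl3 <- applyConstructEdit(lr, "stem1_to_loop")
  expect_true(kl3@truth$features@isKloop)
  expect_false(kl3@truth$features@stem1Minus1)
  diffs3 <- which(strsplit(snoSeq(kl3@record), "")[[1]] !=
                    strsplit(snoSeq(lr@record), "")[[1]])
  expect_true(all(diffs3 %in% pos[c("minus1_b", "minus2_b")]))

  # kl4 analogue from the kl2 state: dropping -1 leaves the tandem pairs
  kl4 <- applyConstructEdit(kl2, "remove_minus1")
  expect_false(kl4@truth$features@stem1Minus1)
  expect_equal(kl4@truth$category, "TANDEM_NO_STEM1")

  # inapplicable edits error
  expect_error(applyConstructEdit(kl2, "introduce_sheared2"), "already")
  expect_error(applyConstructEdit(kl3, "stem1_to_loop"), "already")
})

test_that("background composition outside planted elements is near uniform", {
  labeled <- simulateSnoRNAs(60, seed = 75)
  pooled <- character()
  for (lr in labeled) {
    tr <- lr@truth
    seq <- snoSeq(lr@record)
    planted <- c(tr$boxC[1]:tr$boxC[2], tr$boxD[1]:tr$boxD[2])
    if (!is.null(tr$boxCprime)) {
      planted <- c(planted, tr$boxDprime[1]:tr$boxDprime[2],
                   tr$boxCprime[1]:tr$boxCprime[2],
                   # stem I and L1 slots are constrained by construction
                   (tr$boxDprime[2] + 1):(tr$boxDprime[2] + 2),
                   (tr$boxCprime[1] - 3):(tr$boxCprime[1] - 1))
    }
    bg <- setdiff(seq_len(nchar(seq)), planted)
    pooled <- c(pooled, strsplit(seq, "")[[1]][bg])
  }
  n <- length(pooled)
  freqs <- table(factor(pooled, levels = c("A", "C", "G", "U"))) / n
  tol <- 4 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(freqs - 0.25) < tol))
})

test_that("benchmark files round-trip through the standard formats", {
  labeled <- simulateSnoRNAs(6, seed = 76)
  dir <- withr::local_tempdir()
  writeBenchmark(labeled, dir)
  recs <- readSnoRNAFasta(file.path(dir, "snornas.fasta"))
  expect_equal(vapply(recs, snoSeq, character(1)),
               vapply(labeled, function(x) snoSeq(x@record), character(1)))
  truth <- read.delim(file.path(dir, "truth.tsv"))
  expect_equal(truth$category,
               vapply(labeled, function(x) x@truth$category, character(1)))
  subs <- Biostrings::readBStringSet(file.path(dir, "substrates.fasta"))
  expect_gt(length(subs), 0L)
})
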