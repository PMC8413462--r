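test_that("the toy guide-substrate duplex maps the fifth-upstream rule", {
  # guide ACGUACGUACGU at snoRNA positions 10-21, box D CUGA at 22-25;
  # substrate carries the exact reverse complement at positions 3-14
  seq <- paste0("AAAAAAAAA", "ACGUACGUACGU", "CUGA", "AA")
  rec <- SnoRNARecord("toy", seq)
  box <- findBoxD(rec, "D")[[1]]
  expect_equal(boxStart(box), 22L)
  substrate <- "GGACGUACGUACGUGG"
  dx <- findGuideDuplex(rec, box, substrate)
  expect_equal(dx@length, 12L)
  expect_equal(dx@guideRange, c(10L, 21L))
  expect_equal(dx@substrateRange, c(3L, 14L))
  # guide position 17 (= 22 - 5) pairs substrate position 7
  expect_equal(predictMethylationSite(dx, box, rec, substrate), 7L)
})

test_that("unpaired fifth-upstream positions and hopeless substrates are rejected", {
  # only the last 3 guide nucleotides pair: position boxStart-5 is unpaired
  seq <- paste0("AAAAAAAAA", "ACGUACGUACGU", "CUGA", "AA")
  rec <- SnoRNARecord("toy", seq)
  box <- findBoxD(rec, "D")[[1]]
  shortSub <- "CCACGCC"   # pairs only guide positions 19-21 (CGU)
  dx <- findGuideDuplex(rec, box, shortSub, minLen = 3L)
  expect_equal(dx@length, 3L)
  expect_error(predictMethylationSite(dx, box, rec, shortSub),
               "target outside duplex")
  # zero complementarity
  expect_null(findGuideDuplex(rec, box, strrep("A", 20)))
})

test_that("duplex tie-breaks prefer Watson-Crick over wobble, then 5'-most", {
  seq <- paste0("AAAAA", "GGGGGGGG", "CUGA")   # guide GGGGGGGG at 6-13
  rec <- SnoRNARecord("g", seq)
  box <- findBoxD(rec, "D")[[1]]
  # two 8-long placements: the first includes one G:U wobble, the second is
  # all Watson-Crick; the all-WC placement must win despite being 3' of it
  substrate <- paste0("UCCCCCCC", "AA", "CCCCCCCC")
  dx <- findGuideDuplex(rec, box, substrate)
  expect_equal(dx@length, 8L)
  expect_equal(dx@substrateRange, c(11L, 18L))
  expect_equal(dx@nWC, 8L)
  # with equal length and WC count the 5'-most substrate window wins
  substrate2 <- paste0("CCCCCCCC", "AA", "CCCCCCCC")
  dx2 <- findGuideDuplex(rec, box, substrate2)
  expect_equal(dx2@substrateRange, c(1L, 8L))
})

test_that("duplex search equals the brute-force enumeration oracle", {
  set.seed(51)
  agree <- 0L
  for (i in 1:300) {
    guideLen <- sample(6:14, 1)
    seq <- paste0(randomRNA(sample(3:8, 1)), randomRNA(guideLen), "CUGA",
                  randomRNA(2))
    rec <- SnoRNARecord("r", seq)
    box <- findBoxD(rec, "D")[[1]]
    # half the instances contain a planted complementary window
    substrate <- if (i %% 2 == 0) randomRNA(25) else {
      g <- substr(seq, boxStart(box) - guideLen, boxStart(box) - 1L)
      paste0(randomRNA(3), revcompRNA(g), randomRNA(3))
    }
    minLen <- sample(3:6, 1)
    dx <- findGuideDuplex(rec, box, substrate, minLen = minLen)
    oracle <- bruteDuplex(snoSeq(rec), boxStart(box), substrate, minLen = minLen)
    if (is.null(oracle)) {
      expect_null(dx)
    } else {
      expect_equal(dx@length, oracle$L)
      expect_equal(dx@substrateRange[1], oracle$t)
      expect_equal(dx@nWC, oracle$nWC)
      # conservation: reported length equals the number of mapped pairs
      expect_equal(nrow(dx@pairMap), dx@length)
    }
    agree <- agree + 1L
  }
  expect_equal(agree, 300L)
})

test_that("predicted sites equal planted targets across the generator output", {
  labeled <- simulateSnoRNAs(30, seed = 52)
  for (lr in labeled) {
    rec <- lr@record
    ann <- annotateBoxes(rec)
    for (kind in names(lr@truth$substrates)) {
      box <- if (kind == "D") ann@boxD else ann@boxDprime
      sub <- lr@truth$substrates[[kind]]
      dx <- findGuideDuplex(rec, box, sub$seq, substrateId = sub$id)
      expect_false(is.null(dx))
      expect_equal(predictMethylationSite(dx, box, rec, sub$seq), sub$target)
    }
  }
})

test_that("the methylation table validates predictions against known targets", {
  labeled <- simulateSnoRNAs(8, seed = 53)
  recs <- lapply(labeled, function(lr) {
    tr <- lr@truth
    kt <- do.call(rbind, lapply(names(tr$substrates), function(k)
      data.frame(substrate_id = tr$substrates[[k]]$id,
                 position = tr$substrates[[k]]$target,
                 box_kind = k, stringsAsFactors = FALSE)))
    SnoRNARecord(snoId(lr@record), snoSeq(lr@record), knownTargets = kt)
  })
  subs <- unlist(lapply(labeled, function(lr)
    lapply(lr@truth$substrates, function(s) stats::setNames(s$seq, s$id))))
  names(subs) <- unlist(lapply(labeled, function(lr)
    vapply(lr@truth$substrates, function(s) s$id, character(1))))
  anns <- lapply(recs, annotateBoxes)
  tab <- methylationTable(recs, anns, subs)
  expect_gt(nrow(tab), 0L)
  expect_true(all(tab$consistent))
})
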