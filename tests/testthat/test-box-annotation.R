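test_that("box C search honours the 5'-terminal allowance and mismatch cap", {
  rec <- SnoRNARecord("a", "GUGAUGACCCCCCCCCCCCC")
  b <- findBoxC(rec)
  expect_equal(boxStart(b), 1L)
  expect_equal(b@mismatches, 0L)

  rec <- SnoRNARecord("b", "CCAUGAUGACCCCCCCCCCC")
  b <- findBoxC(rec)
  expect_equal(boxStart(b), 3L)   # offset 2 from the 5' end

  # first (and only) match at offset 7 violates the allowance
  rec <- SnoRNARecord("c", "CCCCCCCAUGAUGACCCCCC")
  expect_null(findBoxC(rec))

  # one mismatch tolerated by default, two are not
  rec <- SnoRNARecord("d", "AUGAUCACCCCCCCCCCCCC")
  expect_equal(findBoxC(rec)@mismatches, 1L)
  rec <- SnoRNARecord("e", "AUCAUCACCCCCCCCCCCCC")
  expect_null(findBoxC(rec))
})

test_that("box D search finds exact CUGA and applies the target-anchor rule", {
  rec <- SnoRNARecord("a", paste0(strrep("A", 20), "CUGAUC"))
  cands <- findBoxD(rec, "D")
  expect_length(cands, 1L)
  expect_equal(boxStart(cands[[1]]), 21L)

  # two occurrences; a known guide position keeps only start == guidePos + 5
  seq <- paste0(strrep("A", 10), "CUGA", strrep("A", 6), "CUGA", strrep("A", 4))
  rec <- SnoRNARecord("b", seq)
  all <- findBoxD(rec, "Dprime", searchRegion = c(1, nchar(seq)))
  expect_length(all, 2L)
  kept <- findBoxD(rec, "Dprime", searchRegion = c(1, nchar(seq)),
                   knownTargetGuidePos = 6L)
  expect_length(kept, 1L)
  expect_equal(boxStart(kept[[1]]), 11L)

  expect_length(findBoxD(SnoRNARecord("c", strrep("A", 30)), "D"), 0L)
  expect_error(findBoxD(rec, "D", searchRegion = c(10, 5)), "empty")
  # box D candidates rank 3'-most first
  seq2 <- paste0(strrep("A", 10), "CUGAACUGA")
  r2 <- findBoxD(SnoRNARecord("d", seq2), "D")
  expect_equal(boxStart(r2[[1]]), 16L)
})

test_that("stem II scoring counts canonical pair identities", {
  expect_equal(scoreStemII("AUGAUGA", "CUGA"), 4L)
  # pairs (C,A)x (A,G)ok (U,U)ok (G,C)ok
  expect_equal(scoreStemII("UACAUGU", "CUGA"), 3L)
  # pairs (G,A)ok (U,G)x (G,U)x (C,C)x
  expect_equal(scoreStemII("AUGUGCA", "CUGA"), 1L)
  expect_error(scoreStemII("AUGAUG", "CUGA"), "7 nt")
  expect_error(scoreStemII("AUGAUGA", "CUG"), "4 nt")
})

test_that("box C' selection maximizes stem II, reproducing the shifted-window case", {
  # two overlapping 7-mer candidates three nucleotides apart, scoring 3 vs 1:
  # the higher-scoring UACAUGU window must win over AUGUGCA
  seq <- paste0("AUGAUGA",            # box C
                "CCACCACCACCA",       # guide
                "CUGA", "GC", "CCCC", # box D', stem I n side, spacer
                "GC", "A",            # stem I b side, L1
                "UACAUGUGCA",         # candidate windows at 31 and 34
                "CCACCACCACCA",       # guide
                "CUGA")               # box D
  rec <- SnoRNARecord("snR41like", seq)
  ann <- annotateBoxes(rec)
  expect_equal(ann@boxCprime@windowSeq, "UACAUGU")
  expect_equal(ann@boxCprime@score, 3L)
  expect_equal(boxStart(ann@boxCprime), 33L)

  # selected window scores at least as high as every admissible window
  # (exhaustive enumeration oracle)
  dp <- ann@boxDprime
  lo <- boxEnd(dp) + 3L
  hi <- boxStart(ann@boxD) - 6L - 7L
  scores <- vapply(lo:hi, function(s)
    scoreStemII(substr(seq, s, s + 6L), dp@windowSeq), integer(1))
  expect_equal(ann@boxCprime@score, max(scores))

  # interval shorter than a window yields no C'
  short <- SnoRNARecord("s", paste0("AUGAUGA", "CCACCACC", "CUGA", "GCAAA",
                                    "CUGA"))
  dpc <- findBoxD(short, "Dprime", searchRegion = c(8, 19))
  bd <- findBoxD(short, "D")[[1]]
  expect_null(findBoxCprime(short, dpc[[1]], bd))
})

test_that("window offsets recover the printed three-nucleotide shifts", {
  expect_equal(windowOffset("UUGAUGA", "AUGACUA"), 3L)
  expect_equal(windowOffset("UACAUGU", "AUGUGCA"), 3L)
  expect_equal(windowOffset("AUGAUGA", "AUGAUGA"), 0L)
  expect_true(is.na(windowOffset("AAAAAAA", "CCCCCCC")))
  expect_error(windowOffset("AAA", "AAAA"), "equal length")
})

test_that("annotated boxes never overlap and respect the C < D' < C' < D order", {
  labeled <- simulateSnoRNAs(20, seed = 31)
  for (lr in labeled) {
    ann <- annotateBoxes(lr@record)
    boxes <- Filter(Negate(is.null),
                    list(ann@boxC, ann@boxDprime, ann@boxCprime, ann@boxD))
    if (length(boxes) < 2L) next
    starts <- vapply(boxes, boxStart, integer(1))
    ends <- vapply(boxes, boxEnd, integer(1))
    expect_true(all(diff(starts) > 0))            # ordered
    expect_true(all(ends[-length(ends)] < starts[-1]))  # non-overlapping
  }
})

test_that("annotation recovers planted coordinates on the synthetic benchmark", {
  labeled <- simulateSnoRNAs(30, seed = 32)
  for (lr in labeled) {
    ann <- annotateBoxes(lr@record)
    tr <- lr@truth
    expect_equal(boxStart(ann@boxC), tr$boxC[1])
    expect_equal(boxStart(ann@boxD), tr$boxD[1])
    if (is.null(tr$boxDprime)) {
      expect_null(ann@boxDprime)
    } else {
      expect_equal(boxStart(ann@boxDprime), tr$boxDprime[1])
      expect_equal(boxStart(ann@boxCprime), tr$boxCprime[1])
    }
  }
})

test_that("annotation table and BED export carry 1-based and BED conventions", {
  labeled <- simulateSnoRNAs(4, seed = 33)
  recs <- lapply(labeled, function(x) x@record)
  anns <- lapply(recs, annotateBoxes)
  tab <- annotationTable(anns)
  expect_true(all(tab$start >= 1))
  expect_true(all(tab$end > tab$start))
  bed <- withr::local_tempfile(fileext = ".bed")
  lens <- stats::setNames(vapply(recs, function(r) nchar(snoSeq(r)), integer(1)),
                          vapply(recs, snoId, character(1)))
  writeBoxBed(anns, bed, lens)
  fields <- read.table(bed, sep = "\t", stringsAsFactors = FALSE)
  # BED is 0-based half-open: starts shift down by one, ends match
  m <- match(paste(fields$V1, fields$V4), paste(tab$snoRNA_id, tab$box_kind))
  expect_equal(fields$V2, tab$start[m] - 1L)
  expect_equal(fields$V3, tab$end[m])
})
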