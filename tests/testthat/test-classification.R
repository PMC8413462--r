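test_that("motif categories follow the feature rules and partition all inputs", {
  # consensus on both windows
  f <- FeatureSet(TRUE, TRUE, TRUE, TRUE, cprimeConsensus = TRUE,
                  dprimeConsensus = TRUE, stem2Score = 4L)
  expect_equal(classifyMotif(f)@category, "CANONICAL")
  expect_true(classifyMotif(f)@functional)

  # all three required features, non-consensus
  f <- FeatureSet(TRUE, TRUE, TRUE, TRUE, stem2Score = 4L)
  expect_equal(classifyMotif(f)@category, "FUNCTIONAL_NONCANONICAL")

  # tandem sheared pairs without the -1 pair
  f <- FeatureSet(TRUE, TRUE, FALSE, FALSE, stem2Score = 2L)
  expect_equal(classifyMotif(f)@category, "TANDEM_NO_STEM1")
  expect_false(classifyMotif(f)@functional)

  # a missing sheared pair dominates everything else
  f <- FeatureSet(TRUE, FALSE, TRUE, TRUE, stem2Score = 2L)
  expect_equal(classifyMotif(f)@category, "MISSING_SHEARED")

  # the rules are total and deterministic over all boolean feature combinations
  grid <- expand.grid(s1 = c(TRUE, FALSE), s2 = c(TRUE, FALSE),
                      m1 = c(TRUE, FALSE), cc = c(TRUE, FALSE),
                      dc = c(TRUE, FALSE))
  cats <- apply(grid, 1, function(g)
    classifyMotif(FeatureSet(g["s1"], g["s2"], g["m1"], g["m1"],
                             cprimeConsensus = g["cc"],
                             dprimeConsensus = g["dc"]))@category)
  expect_true(all(cats %in% c("CANONICAL", "FUNCTIONAL_NONCANONICAL",
                              "TANDEM_NO_STEM1", "MISSING_SHEARED")))
})

test_that("binding predicates reproduce the construct panel EMSA outcomes", {
  panel <- klPanelFeatures()
  for (i in seq_len(nrow(panel))) {
    f <- panelFeatureSet(panel[i, ])
    expect_equal(predictL7AeBinding(f), panel$l7ae_observed[i],
                 label = paste("L7Ae call for", panel$construct[i]))
    if (!is.na(panel$snu13_observed[i]))
      expect_equal(predictSnu13Binding(f), panel$snu13_observed[i],
                   label = paste("Snu13 call for", panel$construct[i]))
  }
})

test_that("Snu13 recognizability implies a functional classification", {
  set.seed(41)
  for (i in 1:200) {
    f <- FeatureSet(sample(c(TRUE, FALSE), 1), sample(c(TRUE, FALSE), 1),
                    sample(c(TRUE, FALSE), 1), sample(c(TRUE, FALSE), 1),
                    cprimeConsensus = sample(c(TRUE, FALSE), 1),
                    dprimeConsensus = sample(c(TRUE, FALSE), 1),
                    stem2Score = sample(0:4, 1))
    if (predictSnu13Binding(f) %in% c("BINDER", "WEAK"))
      expect_true(classifyMotif(f)@functional)
  }
})

test_that("census counts categories and the non-functional percentage", {
  mk <- function(cat., n) replicate(n, {
    f <- switch(cat.,
      CANONICAL = FeatureSet(TRUE, TRUE, TRUE, TRUE, cprimeConsensus = TRUE,
                             dprimeConsensus = TRUE, stem2Score = 4L),
      FUNCTIONAL_NONCANONICAL = FeatureSet(TRUE, TRUE, TRUE, TRUE),
      TANDEM_NO_STEM1 = FeatureSet(TRUE, TRUE, FALSE, FALSE),
      MISSING_SHEARED = FeatureSet(FALSE, TRUE, TRUE, TRUE))
    if (is.null(f)) NULL else classifyMotif(f)
  }, simplify = FALSE)
  cls <- c(mk("CANONICAL", 2), mk("FUNCTIONAL_NONCANONICAL", 1),
           mk("TANDEM_NO_STEM1", 4), mk("MISSING_SHEARED", 3))
  rep <- census(cls)
  expect_equal(rep@nTotal, 10L)
  expect_equal(rep@nCanonical, 2L)
  expect_equal(rep@nFunctionalNoncanonical, 1L)
  expect_equal(rep@nTandemNoStem1, 4L)
  expect_equal(rep@nMissingSheared, 3L)
  expect_equal(rep@fractionNonfunctional, 70)

  # invariant under permutation
  set.seed(42)
  rep2 <- census(sample(cls))
  expect_equal(censusAsList(rep2), censusAsList(rep))

  expect_equal(census(mk("CANONICAL", 1))@fractionNonfunctional, 0)
  expect_error(census(list()), "empty")
})

test_that("EMSA saturation gives a tenfold K_D upper bound in nM", {
  expect_equal(boundValue(kdUpperBound(2)), 200)
  expect_equal(boundValue(kdUpperBound(5)), 500)
  expect_equal(kdUpperBound(1.4)@direction, "upper")
  expect_error(kdUpperBound(0), "positive")
  expect_error(kdUpperBound(-1), "positive")
})

test_that("end-to-end classification recovers planted categories", {
  labeled <- simulateSnoRNAs(25, seed = 43)
  cls <- classifyRecords(lapply(labeled, function(x) x@record))
  planted <- vapply(labeled, function(x) x@truth$category, character(1))
  got <- vapply(cls, function(x) x@category, character(1))
  expect_equal(got, planted)
  tab <- classificationTable(cls)
  expect_equal(nrow(tab), 25L)
  expect_true(all(tab$functional ==
                    (tab$category %in% c("CANONICAL", "FUNCTIONAL_NONCANONICAL"))))
})
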