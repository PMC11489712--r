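test_that("a fully optimal key scores zero suboptimal criteria", {
  k <- generateTopology(8, 1, 3, illustrationRate = 1)
  k@scope$isEmendation <- FALSE
  meta <- optimalMeta(keyId(k))
  r <- scoreKey(k, meta)
  expect_identical(nSuboptimal(r), 0L)
  expect_equal(pctSuboptimal(r), 0)
  # audit trail is complete: every applicable verdict names its evidence
  expect_true(all(nzchar(r@evidence[verdicts(r) != "not-applicable"])))
})

test_that("three injected criterion failures with all criteria applicable", {
  cfg <- keyGenConfig(8, 1, seed = 9, retracing = FALSE,
                      defectRates = list("monothetic" = 1),
                      illustrationRate = 1)
  gen <- generateKey(cfg)
  k <- gen$key
  # swap the leads of an eligible couplet by hand to create a leap-frog
  cps <- couplets(k)
  i <- which(vapply(cps, function(cp)
    all(!is.na(vapply(cp@leads, function(l) l@targetCouplet, integer(1)))),
    logical(1)))[1]
  cps[[i]] <- Couplet(coupletNumber(cps[[i]]), leads(cps[[i]])[c(2, 1)])
  k <- Key(cps, keyId = keyId(k), scope = list(isEmendation = TRUE))
  meta <- optimalMeta(keyId(k))
  meta$emendationStandalone <- TRUE

  r <- scoreKey(k, meta)
  # criteria 6 (leap-frog), 8 (no retracing), 10 (monothetic) fail;
  # criterion 17 applicable-optimal via the emendation fixture, 4 via the
  # stated restrictions: all seventeen applicable
  expect_identical(nApplicable(r), 17L)
  expect_identical(nSuboptimal(r), 3L)
  expect_equal(pctSuboptimal(r), 100 * 3 / 17)
  expect_equal(round(pctSuboptimal(r), 1), 17.6)
  expect_identical(unname(verdicts(r)[c("c6", "c8", "c10")]),
                   rep("suboptimal", 3))
})

test_that("not-applicable handling: single-couplet and emendation keys", {
  k <- parseKey("1 Wings present Genus A\n– Wings absent Genus B")@key
  meta <- optimalMeta("key")
  meta$imagePlacement <- "dispersed"
  r <- scoreKey(k, meta)
  # retracing is N/A for a single couplet; the key has no images so
  # placement is N/A too; it is not an emendation
  expect_identical(unname(verdicts(r)["c8"]), "not-applicable")
  expect_identical(unname(verdicts(r)["c14"]), "not-applicable")
  expect_identical(unname(verdicts(r)["c17"]), "not-applicable")
  expect_lte(nApplicable(r), 16L)
  # n = 2 taxa: trivially as fan-shaped as possible
  expect_identical(unname(verdicts(r)["c9"]), "optimal")

  em <- generateTopology(6, 1, 4, illustrationRate = 1)
  em@scope$isEmendation <- TRUE
  metaE <- optimalMeta(keyId(em))
  metaE$emendationStandalone <- FALSE
  rE <- scoreKey(em, metaE)
  expect_identical(unname(verdicts(rE)["c17"]), "suboptimal")
})

test_that("criterion 9 is N/A for keys outside the fan/comb bounds", {
  tri <- Key(list(Couplet(1L, list(Lead("a b", "Genus_A"),
                                   Lead("c d", "Genus_B"),
                                   Lead("e f", "Genus_C")))), keyId = "t")
  r <- scoreKey(tri, optimalMeta("t"))
  expect_identical(unname(verdicts(r)["c9"]), "not-applicable")
})

test_that("adding a scored defect never decreases the suboptimal count", {
  base <- generateTopology(10, 0.5, 21, illustrationRate = 1)
  meta <- optimalMeta(keyId(base))
  r0 <- scoreKey(base, meta)
  for (cat in list(list("monothetic", 1), list("qualifier-word", 2),
                   list("polychotomy", 1), list("leap-frog", 1))) {
    cfg <- keyGenConfig(10, 0.5, seed = 21, illustrationRate = 1,
                        defectRates = setNames(list(cat[[2]]), cat[[1]]))
    gen <- generateKey(cfg)
    r1 <- scoreKey(gen$key, meta)
    expect_gte(nSuboptimal(r1), nSuboptimal(r0))
  }
})

test_that("mismatched inputs are rejected by key identity", {
  k <- fanKey4()
  other <- computeMetrics(combKeyFixture(4))
  expect_error(scoreKey(k, optimalMeta("fan-4"), metrics = other),
               "different key")
  expect_error(scoreKey(k, optimalMeta("not-this-key")), "different key")
})

test_that("corpus rubric summary uses the sample standard deviation", {
  rs <- lapply(c(2, 4, 6), makeRubric)
  s <- corpusRubricSummary(rs)
  expect_equal(s$meanSuboptimal, 4)
  expect_equal(s$sdSuboptimal, 2)
  expect_identical(s$minSuboptimal, 2L)
  expect_identical(s$maxSuboptimal, 6L)
  expect_equal(s$meanPct, 100 * 4 / 17)

  one <- corpusRubricSummary(rs[1])
  expect_equal(one$sdSuboptimal, 0)
  expect_false(one$sdDefined)

  tab <- rubricAsTable(rs)
  expect_identical(nrow(tab), 3L)
  expect_identical(tab$nSuboptimal, c(2L, 4L, 6L))
  expect_identical(tab$c1, rep("suboptimal", 3))
})
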