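test_that("the canonical two-lead example parses to its exact structure", {
  rep <- parseKey(methodsExampleText)
  k <- rep@key
  expect_length(couplets(k), 1)
  cp <- couplets(k)[[1]]
  expect_identical(coupletNumber(cp), 3L)
  expect_identical(retraceRef(cp), 2L)
  expect_length(leads(cp), 2)
  expect_identical(leadFeatures(leads(cp)[[1]]),
                   c("Head longer than wide",
                     "hind tibia with apicoventral spines"))
  expect_identical(leadTarget(leads(cp)[[1]]), 9L)
  expect_identical(leadFeatures(leads(cp)[[2]]),
                   c("Head shorter than wide",
                     "hind tibia lacking apicoventral spines, surface flat"))
  expect_identical(leadTarget(leads(cp)[[2]]), 4L)
  expect_identical(nrow(rep@unparsedLines), 0L)
})

test_that("a minimal single-couplet key parses with taxon targets", {
  rep <- parseKey("1 Wings present Genus A\n– Wings absent Genus B")
  k <- rep@key
  expect_length(couplets(k), 1)
  expect_identical(keyTaxa(k), c("Genus A", "Genus B"))
  expect_true(is.na(retraceRef(couplets(k)[[1]])))
})

test_that("polychotomies are captured with a warning, not dropped", {
  rep <- parseKey(c("1 Eyes bare Genus A",
                    "– Eyes hairy Genus B",
                    "– Eyes reduced Genus C"))
  expect_length(leads(couplets(rep@key)[[1]]), 3)
  expect_true(any(rep@warnings$category == "polychotomy"))
  expect_identical(keyStyle(rep@key), "mixed-polychotomous")
})

test_that("primed repeat-number leads and ancillary material are accepted", {
  rep <- parseKey(c("1. Pronotum densely punctate 2",
                    "1'. Pronotum smooth [southern Chile] Genus A",
                    "2(1) Eyes bare Genus B",
                    "– Eyes hairy Genus C"))
  k <- rep@key
  expect_length(couplets(k), 2)
  ld2 <- leads(couplets(k)[[1]])[[2]]
  expect_identical(ld2@ancillary, "southern Chile")
  expect_identical(leadTarget(ld2), "Genus A")
  expect_identical(nrow(rep@unparsedLines), 0L)
})

test_that("figure citations are extracted but kept within the feature text", {
  rep <- parseKey(c("1 Clypeus convex in profile (Fig. 3A) 2",
                    "– Clypeus flat in profile (Figs 3B, 4) Genus A",
                    "2(1) Eyes bare Genus B",
                    "– Eyes hairy Genus C"))
  lds <- leads(couplets(rep@key)[[1]])
  expect_identical(figureRefs(lds[[1]]), "Fig. 3A")
  expect_identical(figureRefs(lds[[2]]), "Figs 3B, 4")
  expect_match(leadFeatures(lds[[1]])[1], "Fig\\. 3A")
  # parenthesized figure citations are not mistaken for ancillary text
  expect_true(is.na(lds[[1]]@ancillary))
})

test_that("yoked letter-pair keys map onto the couplet model", {
  rep <- parseKey(c("A. Ocelli present 2",
                    "AA. Ocelli absent Genus C",
                    "B. Eyes bare Genus A",
                    "BB. Eyes hairy Genus B"))
  k <- rep@key
  expect_identical(keyStyle(k), "yoked")
  expect_length(couplets(k), 2)
  expect_true(any(rep@warnings$category == "yoked-style"))
  expect_identical(leadTarget(leads(couplets(k)[[1]])[[1]]), 2L)
})

test_that("multi-genus leads and author strings stay in the taxon target", {
  rep <- parseKey(c("1 Eyes bare Genus A and Genus B",
                    "– Eyes hairy Aus Smith"))
  lds <- leads(couplets(rep@key)[[1]])
  expect_identical(leadTarget(lds[[1]]), "Genus A and Genus B")
  expect_identical(leadTarget(lds[[2]]), "Aus Smith")
  expect_true(any(detectStyle(rep@key)$category == "multi-taxon-lead"))
})

test_that("no input line is silently dropped", {
  txt <- c("Key to the genera of Examplidae",
           "1 Eyes bare Genus A",
           "this line is prose, not a lead",
           "– Eyes hairy Genus B")
  rep <- parseKey(txt)
  expect_identical(rep@unparsedLines$text, "this line is prose, not a lead")
  expect_identical(keyTitle(rep@key), "Key to the genera of Examplidae")
  # consumed + unparsed covers every non-blank line
  expect_identical(nrow(rep@unparsedLines) + 3L, length(txt))
})

test_that("text without any couplet header is rejected", {
  expect_error(parseKey("no key here\njust prose"), "not look like")
  expect_error(parseKey("   \n  "), "empty")
})

test_that("parse-render round trip is the identity on generated keys", {
  for (seed in 1:40) {
    n <- 2 + (seed * 7) %% 30
    b <- (seed %% 5) / 4
    k <- generateTopology(n, b, seed,
                          illustrationRate = (seed %% 3) / 3,
                          retracing = seed %% 2 == 0)
    rep <- parseKey(renderKey(k))
    expect_true(keysEqual(k, rep@key), label = sprintf("seed %d", seed))
    expect_identical(nrow(rep@unparsedLines), 0L)
  }
})

test_that("rendering refuses dangling references and renders retrace refs", {
  dangle <- Key(list(
    Couplet(1L, list(Lead("a b", 12L), Lead("c d", "Genus_001")))),
    keyId = "dangle")
  expect_error(renderKey(dangle), "dangling")

  txt <- renderKey(combKeyFixture(4, retracing = TRUE))
  lns <- strsplit(txt, "\n")[[1]]
  headers <- grep("^[0-9]", lns, value = TRUE)
  expect_match(headers[2], "^2\\(1\\)")
  expect_match(headers[3], "^3\\(2\\)")
  expect_match(lns[2], "^– ")
})
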