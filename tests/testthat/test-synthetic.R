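test_that("a fixed seed reproduces key text and ground truth exactly", {
  cfg <- keyGenConfig(14, 0.5, seed = 5,
                      defectRates = list("leap-frog" = 1L, "monothetic" = 2L),
                      illustrationRate = 0.4)
  g1 <- generateKey(cfg)
  g2 <- generateKey(cfg)
  expect_identical(renderKey(g1$key), renderKey(g2$key))
  expect_identical(g1$groundTruth$injected, g2$groundTruth$injected)
  # and a different seed changes the key
  g3 <- generateKey(keyGenConfig(14, 0.5, seed = 6,
                                 defectRates = list("leap-frog" = 1,
                                                    "monothetic" = 2),
                                 illustrationRate = 0.4))
  expect_false(identical(renderKey(g1$key), renderKey(g3$key)))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  invisible(generateTopology(10, 0.5, 42))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("balance endpoints reach the comb and fan closed forms", {
  for (n in c(4, 6, 16, 33, 128)) {
    mComb <- computeMetrics(generateTopology(n, 0, seed = n))
    expect_equal(mComb@sActual, meanStepsComb(n), tolerance = 1e-9,
                 label = sprintf("comb n=%d", n))
    mFan <- computeMetrics(generateTopology(n, 1, seed = n))
    expect_equal(mFan@sActual, meanStepsFan(n), tolerance = 1e-9,
                 label = sprintf("fan n=%d", n))
    expect_true(mFan@isMaxFan)
  }
  # the 16-taxon comb runs from one to 15 couplets deep
  expect_identical(computeMetrics(generateTopology(16, 0, 1))@depthRange,
                   c(1L, 15L))
})

test_that("every injected defect locus exists in the emitted key", {
  for (seed in 1:25) {
    cfg <- keyGenConfig(6 + (seed * 3) %% 20, 0.5, seed = seed,
      defectRates = list("leap-frog" = 1L, "numbering-error" = 1L,
                         "polychotomy" = 1L, "looped" = 1L, "monothetic" = 1L,
                         "qualifier-word" = 1L, "uncontrasted" = 1L,
                         "duplicate-taxon" = 1L))
    g <- generateKey(cfg)
    nums <- vapply(couplets(g$key), coupletNumber, integer(1))
    gt <- g$groundTruth$injected
    loci <- gt$couplet[!is.na(gt$couplet)]
    expect_true(all(loci %in% nums), label = sprintf("seed %d", seed))
    expect_s4_class(g$groundTruth$trueMetrics, "KeyMetrics")
  }
})

test_that("lint recovers injected defects at their exact loci", {
  det <- c("leap-frog" = "leap-frog", "numbering-error" = "numbering-error",
           "polychotomy" = "polychotomy", "looped" = "looped",
           "monothetic" = "monothetic-couplet",
           "qualifier-word" = "indecisive-feature",
           "uncontrasted" = "uncontrasted-feature")
  for (seed in 1:20) {
    cfg <- keyGenConfig(10 + (seed * 5) %% 15, 0.4, seed = 100 + seed,
      defectRates = list("leap-frog" = 1L, "numbering-error" = 1L,
                         "polychotomy" = 1L, "looped" = 1L,
                         "monothetic" = 1L, "qualifier-word" = 1L,
                         "uncontrasted" = 1L))
    g <- generateKey(cfg)
    d <- lintKey(g$key)
    gt <- g$groundTruth$injected
    for (i in seq_len(nrow(gt))) {
      cat <- det[[gt$category[i]]]
      hit <- d$category == cat &
        (is.na(gt$couplet[i]) | d$couplet == gt$couplet[i])
      expect_true(any(hit, na.rm = TRUE),
                  label = sprintf("seed %d %s@%s", seed, gt$category[i],
                                  gt$couplet[i]))
    }
    # syntactically unambiguous categories raise no false alarms
    for (cat in c("leap-frog", "polychotomy", "looped")) {
      want <- gt$couplet[det[gt$category] == cat]
      got <- unique(d$couplet[d$category == cat])
      expect_setequal(got, want)
    }
  }
})

test_that("monothetic rate one makes every couplet monothetic", {
  cfg <- keyGenConfig(12, 0.5, seed = 3,
                      defectRates = list("monothetic" = 1.0))
  g <- generateKey(cfg)
  expect_equal(detectMonothetic(g$key)$proportion, 1)
})

test_that("corpus metadata respects marginal overrides", {
  corpus <- generateCorpus(400, data.frame(group = "X", prob = 0.5),
                           seed = 11,
                           marginals = list(freelyAvailable = 1,
                                            habitus = 0))
  expect_true(all(corpus$freelyAvailable))
  expect_false(any(corpus$habitusPresent))
  expect_true(all(corpus$nNewGenera[corpus$hasKey] <=
                    corpus$nGeneraInKey[corpus$hasKey]))
  expect_true(all(corpus$nGeneraInKey[corpus$hasKey] >= 2))
})
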