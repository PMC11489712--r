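test_that("leap-frog is flagged only when the first lead jumps", {
  flagged <- parseKey(methodsExampleText)@key
  d <- detectLeapfrog(flagged)
  expect_identical(d$category, "leap-frog")
  expect_identical(d$couplet, 3L)

  standard <- parseKey(c(
    "3(2) Head longer than wide 4",
    "– Head shorter than wide 9"))@key
  expect_identical(nrow(detectLeapfrog(standard)), 0L)

  taxa <- parseKey("1 Eyes bare Genus A\n– Eyes hairy Genus B")@key
  expect_identical(nrow(detectLeapfrog(taxa)), 0L)
})

test_that("retracing support and mismatched references are assessed", {
  ok <- combKeyFixture(6, retracing = TRUE)
  r <- detectRetracing(ok)
  expect_true(r$supportsRetracing)
  expect_identical(nrow(r$defects), 0L)

  # a pure comb with no references still supports retracing in the default
  # mode: every couplet continues directly from the one above it
  none <- combKeyFixture(6, retracing = FALSE)
  r2 <- detectRetracing(none)
  expect_true(r2$supportsRetracing)
  expect_false(detectRetracing(none, strict = TRUE)$supportsRetracing)

  # a balanced key without references has jumps and fails even leniently
  jumpy <- generateTopology(10, 1, 8, retracing = FALSE)
  expect_false(detectRetracing(jumpy)$supportsRetracing)

  tiny <- parseKey("1 Eyes bare Genus A\n– Eyes hairy Genus B")@key
  expect_true(is.na(detectRetracing(tiny)$supportsRetracing))

  # couplet 7(3) where couplet 3's leads do not target 7
  mis <- Key(list(
    Couplet(3L, list(Lead("a b", 4L), Lead("c d", 9L))),
    Couplet(4L, list(Lead("e f", "Genus_A"), Lead("g h", "Genus_B")),
            retraceRef = 3L),
    Couplet(9L, list(Lead("i j", "Genus_C"), Lead("k l", 7L)),
            retraceRef = 3L),
    Couplet(7L, list(Lead("m n", "Genus_D"), Lead("o p", "Genus_E")),
            retraceRef = 3L)), keyId = "mismatch")
  d <- detectRetracing(mis)$defects
  expect_true(any(d$category == "numbering-error" & d$couplet == 7L))
})

test_that("numbering errors cover duplicates, gaps, and cycles", {
  k <- Key(list(
    Couplet(1L, list(Lead("a b", 2L), Lead("c d", "Genus_A"))),
    Couplet(2L, list(Lead("e f", "Genus_B"), Lead("g h", 4L))),
    Couplet(2L, list(Lead("i j", "Genus_C"), Lead("k l", "Genus_D"))),
    Couplet(4L, list(Lead("m n", "Genus_E"), Lead("o p", "Genus_F")))),
    keyId = "dup-gap")
  d <- detectNumberingErrors(k)
  expect_true(any(d$category == "numbering-error" & d$couplet == 2L))
  expect_true(any(d$category == "missing-numbers" & d$couplet == 3L))

  clean <- combKeyFixture(5)
  expect_identical(nrow(detectNumberingErrors(clean)), 0L)

  cyc <- Key(list(
    Couplet(1L, list(Lead("a b", 2L), Lead("c d", "Genus_A"))),
    Couplet(2L, list(Lead("e f", 3L), Lead("g h", "Genus_B"))),
    Couplet(3L, list(Lead("i j", 1L), Lead("k l", "Genus_C")))),
    keyId = "cycle")
  d2 <- detectNumberingErrors(cyc)
  expect_true(any(d2$category == "numbering-error" &
                    grepl("cycle", d2$message)))
})

test_that("monothetic couplets are counted and traced along paths", {
  mono <- parseKey("1 Wings present Genus A\n– Wings absent Genus B")@key
  r <- detectMonothetic(mono)
  expect_true(r$perCouplet[["1"]])
  expect_equal(r$proportion, 1)

  multi <- parseKey(methodsExampleText)@key
  expect_false(detectMonothetic(multi)$perCouplet[["3"]])

  # comb key whose root alone is monothetic: every path crosses the root
  k <- combKeyFixture(4)
  cps <- couplets(k)
  cps[[1]] <- Couplet(1L, list(Lead("Ocelli present", "Genus_001"),
                               Lead("Ocelli absent", 2L)))
  k2 <- Key(cps, keyId = "mono-root")
  r2 <- detectMonothetic(k2)
  expect_equal(r2$proportion, 1 / 3)
  expect_true(r2$allPathsHit)

  # monothetic couplet off the main path does not cover every taxon
  cps2 <- couplets(combKeyFixture(4))
  cps2[[3]] <- Couplet(3L, list(Lead("Ocelli present", "Genus_003"),
                                Lead("Ocelli absent", "Genus_004")),
                       retraceRef = 2L)
  r3 <- detectMonothetic(Key(cps2, keyId = "mono-deep"))
  expect_false(r3$allPathsHit)
})

test_that("parallel and contrast checks pair features by subject", {
  ok <- Couplet(1L, list(
    Lead(c("Head long", "tibia spined"), 2L),
    Lead(c("Head short", "tibia unspined"), 3L)))
  expect_identical(nrow(detectParallelContrast(ok)), 0L)

  nonpar <- Couplet(1L, list(
    Lead(c("Head long", "tibia spined"), 2L),
    Lead(c("tibia unspined", "Head short"), 3L)))
  d <- detectParallelContrast(nonpar)
  expect_true(any(d$category == "non-parallel-features"))

  unc <- Couplet(1L, list(
    Lead(c("Head long", "wing dark"), 2L),
    Lead(c("Head short"), 3L)))
  d2 <- detectParallelContrast(unc)
  expect_true(any(d2$category == "uncontrasted-feature" & d2$lead == 1L))
  expect_match(d2$message[d2$category == "uncontrasted-feature"], "wing dark")

  blocked <- Couplet(1L, list(
    Lead("Head long", 2L), Lead("tibia unspined", 3L)))
  d3 <- detectParallelContrast(blocked)
  expect_true(any(d3$category == "uncontrasted-feature" & is.na(d3$lead)))
})

test_that("ambiguity detection flags qualifiers, relatives, and overlaps", {
  overlap <- Couplet(1L, list(
    Lead("body length 9–12 mm", "Genus_A"),
    Lead("body length 11–15 mm", "Genus_B")))
  d <- detectAmbiguity(overlap)
  expect_true(any(grepl("overlap", d$message)))

  disjoint <- Couplet(1L, list(
    Lead("body length 9–12 mm", "Genus_A"),
    Lead("body length 14–15 mm", "Genus_B")))
  expect_false(any(grepl("overlap", detectAmbiguity(disjoint)$message)))

  resolved <- Couplet(1L, list(
    Lead("surface strongly convex (Fig. 3A)", "Genus_A",
         figureRefs = "Fig. 3A"),
    Lead("surface weakly convex (Fig. 3B)", "Genus_B",
         figureRefs = "Fig. 3B")))
  expect_identical(nrow(detectAmbiguity(resolved)), 0L)

  unresolved <- Couplet(1L, list(
    Lead("surface strongly convex", "Genus_A"),
    Lead("surface weakly convex", "Genus_B")))
  d2 <- detectAmbiguity(unresolved)
  expect_true(any(d2$category == "unresolved-relative-statement"))
  expect_true(any(d2$category == "fully-indecisive-couplet"))

  qual <- Couplet(1L, list(
    Lead("punctures usually dense", "Genus_A"),
    Lead("punctures sparse", "Genus_B")))
  d3 <- detectAmbiguity(qual)
  expect_true(any(d3$category == "indecisive-feature" &
                    grepl("qualifier", d3$message)))

  # a relative marker quantified by an explicit ratio is not flagged
  ratio <- Couplet(1L, list(
    Lead("ocellar distance wider (2x ocellar diameter)", "Genus_A"),
    Lead("ocellar distance narrower (1.2x ocellar diameter)", "Genus_B")))
  expect_identical(nrow(detectAmbiguity(ratio)), 0L)
  # a bare comparative with a stated standard ("longer than wide") passes
  than <- Couplet(1L, list(
    Lead("Head longer than wide", "Genus_A"),
    Lead("Head shorter than wide", "Genus_B")))
  expect_identical(nrow(detectAmbiguity(than)), 0L)
})

test_that("illustration coverage is classified none / partial / all-leads", {
  bare <- combKeyFixture(4)
  r <- detectIllustrationCoverage(bare)
  expect_equal(r$propLeadsIllustrated, 0)
  expect_identical(r$coverageClass, "none")

  half <- parseKey(c("1 Eyes bare (Fig. 1) 2",
                     "– Eyes hairy Genus A",
                     "2(1) Ocelli present (Fig. 2) Genus B",
                     "– Ocelli absent Genus C"))@key
  r2 <- detectIllustrationCoverage(half)
  expect_equal(r2$propLeadsIllustrated, 0.5)
  expect_identical(r2$coverageClass, "partial")

  full <- generateTopology(5, 1, 2, illustrationRate = 1)
  r3 <- detectIllustrationCoverage(full)
  expect_identical(r3$coverageClass, "all-leads")
})

test_that("style detection reports polychotomy, loop, and duplicates", {
  tri <- Key(list(Couplet(1L, list(Lead("a b", "Genus_A"),
                                   Lead("c d", "Genus_B"),
                                   Lead("e f", "Genus_C")))), keyId = "t")
  expect_true(any(detectStyle(tri)$category == "polychotomy"))

  looped <- Key(list(
    Couplet(1L, list(Lead("a b", 2L), Lead("c d", 5L))),
    Couplet(2L, list(Lead("e f", "Genus_A"), Lead("g h", 5L))),
    Couplet(5L, list(Lead("i j", "Genus_B"), Lead("k l", "Genus_C")))),
    keyId = "loop")
  d <- detectStyle(looped)
  expect_true(any(d$category == "looped" & d$couplet == 5L))

  dup <- Key(list(
    Couplet(1L, list(Lead("a b", "Genus_A"), Lead("c d", 2L))),
    Couplet(2L, list(Lead("e f", "genus_a"), Lead("g h", "Genus_B")),
            retraceRef = 1L)), keyId = "dup")
  expect_true(any(detectStyle(dup)$category == "duplicate-taxon"))
})

test_that("lint is deterministic and clean generated keys are defect-free", {
  k <- generateTopology(12, 0.4, 11, illustrationRate = 1)
  expect_identical(lintKey(k)[, 1:4], lintKey(k)[, 1:4])
  syntactic <- c("leap-frog", "numbering-error", "missing-numbers",
                 "polychotomy", "looped", "dangling-reference",
                 "unreachable-couplet", "uncontrasted-feature",
                 "indecisive-feature", "fully-indecisive-couplet",
                 "monothetic-couplet")
  for (seed in 1:15) {
    k <- generateTopology(2 + (seed * 5) %% 30, (seed %% 4) / 3, seed,
                          illustrationRate = 1)
    d <- lintKey(k)
    expect_identical(nrow(d[d$category %in% syntactic, ]), 0L,
                     label = sprintf("seed %d", seed))
  }
})
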