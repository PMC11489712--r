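# Hand-built fixture keys, constructed in code.

# A strict comb: couplet i keys out Genus i and continues to couplet i+1.
combKeyFixture <- function(n = 4, retracing = TRUE) {
  cps <- lapply(seq_len(n - 1), function(i) {
    last <- i == n - 1
    Couplet(i, list(
      Lead(c("Head longer than wide", "eyes bare"),
           target = sprintf("Genus_%03d", i)),
      Lead(c("Head shorter than wide", "eyes hairy"),
           target = if (last) sprintf("Genus_%03d", n) else i + 1L)),
      retraceRef = if (retracing && i > 1) i - 1L else NA_integer_)
  })
  Key(cps, keyId = sprintf("comb-%d", n))
}

# Balanced 4-taxon fan.
fanKey4 <- function() {
  Key(list(
    Couplet(1L, list(Lead("Ocelli present", 2L),
                     Lead("Ocelli absent", 3L))),
    Couplet(2L, list(Lead("Eyes bare", "Genus_001"),
                     Lead("Eyes hairy", "Genus_002")), retraceRef = 1L),
    Couplet(3L, list(Lead("Mandible bidentate", "Genus_003"),
                     Lead("Mandible tridentate", "Genus_004")),
            retraceRef = 1L)),
    keyId = "fan-4")
}

# Metadata that scores optimal on every applicable criterion.
optimalMeta <- function(keyId = "key") {
  paperMetadata(keyId = keyId, freelyAvailable = TRUE,
    keyTermLocation = c("title", "abstract"), scopeStatementPresent = TRUE,
    sexRestrictionStated = TRUE, casteRestrictionStated = TRUE,
    diagnosisCoverage = "all", habitusPresent = TRUE,
    imagePlacement = "adjacent", emendationStandalone = NA)
}

# A RubricResult with exactly k suboptimal verdicts, all 17 applicable.
makeRubric <- function(k, keyId = sprintf("r%d", k)) {
  v <- setNames(rep("optimal", 17), paste0("c", 1:17))
  v[seq_len(k)] <- "suboptimal"
  new("RubricResult", keyId = keyId, verdicts = v,
      evidence = setNames(rep("fixture", 17), paste0("c", 1:17)),
      nSuboptimal = as.integer(k), nApplicable = 17L,
      pctSuboptimal = 100 * k / 17)
}

methodsExampleText <- c(
  "3(2) Head longer than wide; hind tibia with apicoventral spines 9",
  "– Head shorter than wide; hind tibia lacking apicoventral spines, surface flat 4")
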