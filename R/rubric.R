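#' @include lint.R
NULL

#' Paper-level metadata record
#'
#' One record describes the paper that carries a key: availability,
#' discoverability, scope statements, confirmation aids (diagnoses, habitus
#' images), and counts of genera. These are the fields the rubric consumes
#' alongside the key itself. Logical fields admit NA for "not applicable"
#' (e.g. caste restriction for a non-social taxon).
#'
#' @param paperId,keyId Identifiers.
#' @param order,journal Grouping fields.
#' @param freelyAvailable,availableViaLibrary Availability of the text.
#' @param keyTermLocation Character vector, subset of
#'   \code{c("title","abstract","keywords")}; empty means the word "key" is
#'   not discoverable.
#' @param scopeStatementPresent Were the features making the key relevant to
#'   a specimen stated?
#' @param scopeStatementLocation One of "above-key", "below-key",
#'   "introduction", "results-elsewhere", "methods", "diagnosis", or NA.
#' @param sexRestrictionStated,casteRestrictionStated Logical or NA when the
#'   question does not arise.
#' @param diagnosisCoverage One of "none", "new-genera-only", "some-others",
#'   "all".
#' @param habitusPresent,habitusKind Habitus image and its kind
#'   ("photograph", "drawing", "SEM", or NA).
#' @param imagePlacement One of "adjacent", "adjacent-page", "hyperlinked",
#'   "grouped-at-key", "dispersed", "none".
#' @param nNewGenera,nGeneraInKey Genus counts; nNewGenera must not exceed
#'   nGeneraInKey when a key exists.
#' @param keyInSupplementOnly,emendationStandalone Logical (the latter NA
#'   unless the key is an emendation).
#' @param hasKey Does the paper include a key at all?
#' @return One-row data.frame.
#' @export
paperMetadata <- function(paperId = "paper", keyId = "key",
    order = NA_character_, journal = NA_character_,
    freelyAvailable = TRUE, availableViaLibrary = FALSE,
    keyTermLocation = "abstract", scopeStatementPresent = TRUE,
    scopeStatementLocation = "above-key",
    sexRestrictionStated = NA, casteRestrictionStated = NA,
    diagnosisCoverage = "all", habitusPresent = TRUE,
    habitusKind = "photograph", imagePlacement = "adjacent",
    nNewGenera = 1L, nGeneraInKey = 2L,
    keyInSupplementOnly = FALSE, emendationStandalone = NA,
    hasKey = TRUE) {
  if (isTRUE(hasKey) && nNewGenera > nGeneraInKey)
    stop("nNewGenera must not exceed nGeneraInKey when a key exists")
  data.frame(paperId = paperId, keyId = keyId, order = order,
    journal = journal, freelyAvailable = freelyAvailable,
    availableViaLibrary = availableViaLibrary,
    keyTermLocation = paste(keyTermLocation, collapse = ","),
    scopeStatementPresent = scopeStatementPresent,
    scopeStatementLocation = scopeStatementLocation,
    sexRestrictionStated = sexRestrictionStated,
    casteRestrictionStated = casteRestrictionStated,
    diagnosisCoverage = diagnosisCoverage,
    habitusPresent = habitusPresent, habitusKind = habitusKind,
    imagePlacement = imagePlacement, nNewGenera = as.integer(nNewGenera),
    nGeneraInKey = as.integer(nGeneraInKey),
    keyInSupplementOnly = keyInSupplementOnly,
    emendationStandalone = emendationStandalone, hasKey = hasKey,
    stringsAsFactors = FALSE)
}

#' Score a key against the 17-criterion suboptimality rubric
#'
#' Each criterion is judged optimal, suboptimal, or not-applicable:
#' \enumerate{
#'   \item the key (i.e. its paper) was available, freely or via a library;
#'   \item the word "key" appears in title, abstract, or keywords;
#'   \item the features making the key relevant to a specimen were stated
#'     (auto-optimal for family-rank keys, where instructions may be deemed
#'     unnecessary; configurable);
#'   \item sex/caste restrictions were stated where they apply;
#'   \item no formatting (numbering) errors;
#'   \item no leap-frog couplets;
#'   \item all couplets dichotomous;
#'   \item retracing possible (N/A for keys of two couplets or fewer);
#'   \item the key is as fan-shaped as possible (N/A for keys excluded from
#'     the fan/comb bounds; auto-optimal for three or fewer taxa);
#'   \item no monothetic couplets;
#'   \item all features contrasted;
#'   \item no couplet entirely indecisive;
#'   \item at least one image cited for every lead;
#'   \item images conveniently placed (adjacent, hyperlinked, or grouped at
#'     the key; N/A when no image exists to place);
#'   \item all taxa diagnosed;
#'   \item a habitus image provided;
#'   \item the key, if an emendation, stands alone (N/A otherwise).
#' }
#' Each verdict carries the defect category or metadata field that decided
#' it, as an audit trail.
#'
#' @param key A \linkS4class{Key}.
#' @param meta One-row metadata data.frame from \code{\link{paperMetadata}}.
#' @param metrics \linkS4class{KeyMetrics} for the same key.
#' @param defects Defect table from \code{\link{lintKey}} for the same key.
#' @param familyRankAutoOptimal Score criterion 3 optimal for family-rank
#'   keys regardless of the scope statement.
#' @return A \linkS4class{RubricResult}.
#' @export
scoreKey <- function(key, meta, metrics = computeMetrics(key),
                     defects = lintKey(key),
                     familyRankAutoOptimal = TRUE) {
  if (nzchar(metrics@keyId) && nzchar(key@keyId) &&
      !identical(metrics@keyId, key@keyId))
    stop("metrics were computed from a different key (keyId mismatch)")
  if (!is.null(meta$keyId) && !is.na(meta$keyId) && nzchar(meta$keyId) &&
      nzchar(key@keyId) && !identical(meta$keyId, key@keyId))
    stop("metadata describe a different key (keyId mismatch)")

  has <- function(cat) any(defects$category %in% cat)
  v <- setNames(rep("optimal", 17L), paste0("c", 1:17))
  ev <- setNames(rep("", 17L), paste0("c", 1:17))
  set <- function(i, verdict, why) {
    v[[paste0("c", i)]] <<- verdict
    ev[[paste0("c", i)]] <<- why
  }

  # 1 availability
  if (isTRUE(meta$freelyAvailable) || isTRUE(meta$availableViaLibrary))
    set(1, "optimal", "freelyAvailable/availableViaLibrary")
  else set(1, "suboptimal", "paper not available")

  # 2 discoverability
  locs <- strsplit(meta$keyTermLocation %||% "", ",")[[1]]
  locs <- locs[nzchar(locs) & locs != "none"]
  if (length(locs)) set(2, "optimal", paste("key term in",
                                            paste(locs, collapse = "/")))
  else set(2, "suboptimal", "word 'key' absent from title/abstract/keywords")

  # 3 scope statement
  famRank <- identical(key@scope$rank, "family")
  if (famRank && familyRankAutoOptimal)
    set(3, "optimal", "family-rank key: scope statement deemed unnecessary")
  else if (isTRUE(meta$scopeStatementPresent))
    set(3, "optimal", "scopeStatementPresent")
  else set(3, "suboptimal", "no statement of what the key applies to")

  # 4 sex/caste restriction statements (disjunction of failures; N/A when
  # neither question arises)
  sexF <- identical(meta$sexRestrictionStated, FALSE)
  casteF <- identical(meta$casteRestrictionStated, FALSE)
  sexNA <- is.na(meta$sexRestrictionStated)
  casteNA <- is.na(meta$casteRestrictionStated)
  if (sexF || casteF)
    set(4, "suboptimal", paste0(if (sexF) "sex restriction unstated " else "",
                                if (casteF) "caste restriction unstated" else ""))
  else if (sexNA && casteNA)
    set(4, "not-applicable", "no sex/caste restriction arises")
  else set(4, "optimal", "restrictions stated where applicable")

  # 5 formatting errors
  if (has(c("numbering-error", "missing-numbers")))
    set(5, "suboptimal", "numbering-error/missing-numbers defects")
  else set(5, "optimal", "no numbering defects")

  # 6 leap-frog
  if (has("leap-frog")) set(6, "suboptimal", "leap-frog defects")
  else set(6, "optimal", "no leap-frog couplets")

  # 7 dichotomous
  if (has("polychotomy")) set(7, "suboptimal", "polychotomy defects")
  else set(7, "optimal", "all couplets dichotomous")

  # 8 retracing
  retr <- attr(defects, "retracing")
  supports <- if (!is.null(retr)) retr$supportsRetracing
              else !has("no-retracing")
  if (length(key@couplets) <= 2L || is.na(supports))
    set(8, "not-applicable", "key has two couplets or fewer")
  else if (isTRUE(supports)) set(8, "optimal", "retracing supported")
  else set(8, "suboptimal", "no retrace references")

  # 9 fan-shapedness
  if (is.na(metrics@sMin) || is.na(metrics@sActual))
    set(9, "not-applicable",
        "key excluded from fan/comb bounds (polychotomy/loop)")
  else if (metrics@nTaxa <= 3L)
    set(9, "optimal", "three or fewer taxa: trivially as fan-shaped as possible")
  else if (isTRUE(metrics@isMaxFan))
    set(9, "optimal", "mean steps equal the fan-shaped minimum")
  else set(9, "suboptimal",
           sprintf("mean steps %.3f exceed fan minimum %.3f",
                   metrics@sActual, metrics@sMin))

  # 10 monothetic couplets
  if (has("monothetic-couplet")) set(10, "suboptimal", "monothetic-couplet defects")
  else set(10, "optimal", "no monothetic couplets")

  # 11 contrast
  if (has("uncontrasted-feature")) set(11, "suboptimal", "uncontrasted-feature defects")
  else set(11, "optimal", "all features contrasted")

  # 12 decisiveness
  if (has("fully-indecisive-couplet"))
    set(12, "suboptimal", "fully-indecisive-couplet defects")
  else set(12, "optimal", "no entirely indecisive couplet")

  # 13 illustration coverage
  ill <- attr(defects, "illustration")
  cls <- if (!is.null(ill)) ill$coverageClass
         else if (has("unillustrated-lead")) "partial" else "all-leads"
  if (identical(cls, "all-leads")) set(13, "optimal", "every lead illustrated")
  else set(13, "suboptimal", sprintf("illustration coverage: %s", cls))

  # 14 image placement; nothing to place when no images at all
  if (identical(cls, "none") ||
      identical(meta$imagePlacement, "none"))
    set(14, "not-applicable", "no images cited, placement unassessable")
  else if (meta$imagePlacement %in% c("adjacent", "hyperlinked",
                                      "grouped-at-key"))
    set(14, "optimal", sprintf("imagePlacement=%s", meta$imagePlacement))
  else set(14, "suboptimal", sprintf("imagePlacement=%s", meta$imagePlacement))

  # 15 diagnoses
  if (identical(meta$diagnosisCoverage, "all"))
    set(15, "optimal", "all taxa diagnosed")
  else set(15, "suboptimal",
           sprintf("diagnosisCoverage=%s", meta$diagnosisCoverage))

  # 16 habitus
  if (isTRUE(meta$habitusPresent)) set(16, "optimal", "habitus image present")
  else set(16, "suboptimal", "no habitus image")

  # 17 emendation standing alone
  if (!isTRUE(key@scope$isEmendation))
    set(17, "not-applicable", "key is not an emendation")
  else if (isTRUE(meta$emendationStandalone))
    set(17, "optimal", "emendation usable without the previous key")
  else set(17, "suboptimal", "emendation requires the previous key")

  nSub <- sum(v == "suboptimal")
  nApp <- 17L - sum(v == "not-applicable")
  new("RubricResult", keyId = key@keyId, verdicts = v, evidence = ev,
      nSuboptimal = as.integer(nSub), nApplicable = as.integer(nApp),
      pctSuboptimal = if (nApp >= 1L) 100 * nSub / nApp else NA_real_)
}

#' Corpus-level rubric summary
#'
#' Summarizes suboptimal-criterion counts and percentages over many keys
#' with the sample standard deviation (n - 1 denominator). A single result
#' gets SD 0 with \code{sdDefined = FALSE}.
#'
#' @param results List of \linkS4class{RubricResult} objects.
#' @return One-row data.frame: meanSuboptimal, sdSuboptimal, minSuboptimal,
#'   maxSuboptimal, meanPct, sdPct, minPct, maxPct, n, sdDefined.
#' @export
corpusRubricSummary <- function(results) {
  stopifnot(length(results) >= 1)
  counts <- vapply(results, nSuboptimal, integer(1))
  pcts <- vapply(results, pctSuboptimal, numeric(1))
  sdOr0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  data.frame(
    meanSuboptimal = mean(counts), sdSuboptimal = sdOr0(counts),
    minSuboptimal = min(counts), maxSuboptimal = max(counts),
    meanPct = mean(pcts), sdPct = sdOr0(pcts),
    minPct = min(pcts), maxPct = max(pcts),
    n = length(results), sdDefined = length(results) > 1,
    stringsAsFactors = FALSE)
}

#' Export rubric results as a corpus table
#'
#' One row per key: the 17 verdicts, the suboptimal count, and the
#' percentage of applicable criteria that were suboptimal.
#'
#' @param results List of \linkS4class{RubricResult} objects.
#' @return data.frame with columns keyId, c1..c17, nSuboptimal, nApplicable,
#'   pctSuboptimal.
#' @export
rubricAsTable <- function(results) {
  rows <- lapply(results, function(r) {
    out <- data.frame(keyId = r@keyId, stringsAsFactors = FALSE)
    for (i in 1:17) out[[paste0("c", i)]] <- r@verdicts[[paste0("c", i)]]
    out$nSuboptimal <- r@nSuboptimal
    out$nApplicable <- r@nApplicable
    out$pctSuboptimal <- r@pctSuboptimal
    out
  })
  do.call(rbind, rows)
}
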