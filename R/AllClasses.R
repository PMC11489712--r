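#' @import methods
NULL

#' Closed vocabulary of defect categories
#'
#' Every defect a detector can emit belongs to this fixed vocabulary, so
#' downstream tabulation and rubric scoring can rely on exact category names.
#'
#' @return Character vector of valid defect category names.
#' @export
defectCategories <- function() {
  c("numbering-error", "missing-numbers", "leap-frog", "polychotomy",
    "looped", "unreachable-couplet", "dangling-reference", "no-retracing",
    "yoked-style", "monothetic-couplet", "non-parallel-features",
    "uncontrasted-feature", "indecisive-feature", "fully-indecisive-couplet",
    "unresolved-relative-statement", "unillustrated-lead", "multi-taxon-lead",
    "duplicate-taxon")
}

KEY_STYLES <- c("dichotomous", "yoked", "mixed-polychotomous")

#' Lead: one half (or more) of a couplet
#'
#' A lead lists the discriminating features a user must check, and ends either
#' in the number of the couplet to proceed to or in a terminal taxon name.
#' Bracketed non-decisive helper text (typically geographic) is kept separately
#' as ancillary information and excluded from feature-based analyses.
#'
#' @slot ordinal Integer position of the lead within its couplet (1-based).
#' @slot features Character vector of discriminating features, in printed order.
#' @slot targetCouplet Integer couplet number this lead continues to, or NA.
#' @slot targetTaxon Terminal taxon name, or NA. Exactly one target is set.
#' @slot figureRefs Character vector of figure citations found in the lead.
#' @slot ancillary Optional ancillary (non-decisive) text, or NA.
#' @exportClass Lead
setClass("Lead",
  representation(
    ordinal = "integer",
    features = "character",
    targetCouplet = "integer",
    targetTaxon = "character",
    figureRefs = "character",
    ancillary = "character"
  ),
  prototype(
    ordinal = 1L, features = character(), targetCouplet = NA_integer_,
    targetTaxon = NA_character_, figureRefs = character(),
    ancillary = NA_character_
  )
)

setValidity("Lead", function(object) {
  msgs <- character()
  if (length(object@features) < 1L ||
      any(!nzchar(trimws(object@features))))
    msgs <- c(msgs, "a lead must carry at least one non-empty feature")
  hasC <- !is.na(object@targetCouplet)
  hasT <- !is.na(object@targetTaxon) && nzchar(object@targetTaxon)
  if (hasC == hasT)
    msgs <- c(msgs,
      "exactly one of targetCouplet and targetTaxon must be set")
  if (length(object@ordinal) != 1L || is.na(object@ordinal) ||
      object@ordinal < 1L)
    msgs <- c(msgs, "ordinal must be a single integer >= 1")
  if (length(msgs)) msgs else TRUE
})

#' Couplet: a numbered decision point
#'
#' @slot number Integer couplet number as printed.
#' @slot retraceRef Integer number of the couplet that led here (the M of a
#'   printed "N(M)" header), or NA when the key does not support retracing.
#' @slot leads List of \linkS4class{Lead} objects, ordered as printed; length 2
#'   for a dichotomous couplet, more for a polychotomy.
#' @exportClass Couplet
setClass("Couplet",
  representation(number = "integer", retraceRef = "integer", leads = "list"),
  prototype(number = NA_integer_, retraceRef = NA_integer_, leads = list())
)

setValidity("Couplet", function(object) {
  msgs <- character()
  if (length(object@leads) < 2L)
    msgs <- c(msgs, "a couplet needs at least two leads")
  if (!all(vapply(object@leads, is, logical(1), class2 = "Lead")))
    msgs <- c(msgs, "leads must all be Lead objects")
  else {
    ords <- vapply(object@leads, slot, integer(1), name = "ordinal")
    if (!identical(ords, seq_along(object@leads)))
      msgs <- c(msgs, "lead ordinals must run 1..n without gaps")
  }
  if (length(object@number) != 1L || is.na(object@number))
    msgs <- c(msgs, "couplet number must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' Key: a titled, scoped collection of couplets
#'
#' Malformed published keys (duplicate couplet numbers, dangling targets,
#' loops) are deliberately representable: all pathology is reported as defect
#' records by \code{\link{validateKey}} and the lint detectors, never rejected
#' at construction, because real published keys exhibit all of these faults.
#'
#' @slot keyId Identifier string.
#' @slot title Printed title of the key ("" when absent).
#' @slot scope Named list: \code{rank} (taxonomic rank keyed), \code{extent}
#'   (geographic extent category), \code{sex}, \code{caste},
#'   \code{isEmendation} (logical).
#' @slot couplets List of \linkS4class{Couplet} objects in printed order.
#' @slot style One of "dichotomous", "yoked", "mixed-polychotomous".
#' @exportClass Key
setClass("Key",
  representation(
    keyId = "character", title = "character", scope = "list",
    couplets = "list", style = "character"
  ),
  prototype(
    keyId = "key", title = "", scope = list(), couplets = list(),
    style = "dichotomous"
  )
)

setValidity("Key", function(object) {
  msgs <- character()
  if (!all(vapply(object@couplets, is, logical(1), class2 = "Couplet")))
    msgs <- c(msgs, "couplets must all be Couplet objects")
  if (length(object@style) != 1L || !object@style %in% KEY_STYLES)
    msgs <- c(msgs, paste("style must be one of:",
                          paste(KEY_STYLES, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' ParseReport: result of parsing plain key text
#'
#' @slot key The parsed \linkS4class{Key}.
#' @slot warnings Defect table (see \code{\link{emptyDefects}}) of problems
#'   observed while parsing (numbering errors, polychotomies, yoked style).
#' @slot unparsedLines data.frame with columns \code{line}, \code{text}: input
#'   lines that could not be consumed into a couplet, lead, or header.
#' @exportClass ParseReport
setClass("ParseReport",
  representation(key = "Key", warnings = "data.frame",
                 unparsedLines = "data.frame")
)

#' KeyGraph: resolved decision-graph structure over a key
#'
#' @slot root Integer number of the root couplet (NA when undeterminable).
#' @slot parents data.frame with columns \code{couplet},
#'   \code{parentCouplet}, \code{parentLead}: one row per (parent lead ->
#'   child couplet) edge. A couplet appearing with two parents is "looped".
#' @slot taxonPaths Named list mapping normalized taxon name to an integer
#'   vector of path lengths (couplets traversed from the root, root = 1) for
#'   each occurrence of the taxon.
#' @slot taxonLabels Named character vector mapping normalized name to the
#'   first printed form.
#' @slot defects Defect table: looped, unreachable-couplet, dangling-reference.
#' @exportClass KeyGraph
setClass("KeyGraph",
  representation(
    root = "integer", parents = "data.frame", taxonPaths = "list",
    taxonLabels = "character", defects = "data.frame"
  )
)

#' KeyMetrics: path-length statistics for a key
#'
#' Houses the quantities of the comb/fan bound equations: for n terminal taxa,
#' the comb-shaped (caterpillar) mean path S_MAX = ((n+1)/2) - 1/n and the
#' fan-shaped minimum S_MIN = (Q(2^Q - x) + (Q+1)2x)/n with Q = floor(log2 n)
#' and x = n - 2^Q. Keys with polychotomies, loops, or unreachable couplets
#' get NA bounds, mirroring the survey's exclusion rule (the closed forms rely
#' on all couplets being dichotomous).
#'
#' @slot keyId Identifier of the measured key.
#' @slot nTaxa Number of distinct terminal taxa (the n of the bounds).
#' @slot nCouplets Number of couplets present.
#' @slot nCoupletsExpected n - 1, the count expected for a strictly
#'   dichotomous key in which every taxon keys out exactly once.
#' @slot sActual Mean couplets to identification; occurrences of a duplicated
#'   taxon are averaged per taxon first. NA for looped keys.
#' @slot sMax,sMin Closed-form comb and fan bounds (NA when not applicable).
#' @slot q,x Integer decomposition of n: Q = floor(log2 n), x = n - 2^Q.
#' @slot isMaxFan TRUE iff |sActual - sMin| < 1e-9.
#' @slot depthRange Integer (min, max) taxon path length.
#' @exportClass KeyMetrics
setClass("KeyMetrics",
  representation(
    keyId = "character", nTaxa = "integer", nCouplets = "integer",
    nCoupletsExpected = "integer", sActual = "numeric", sMax = "numeric",
    sMin = "numeric", q = "integer", x = "integer", isMaxFan = "logical",
    depthRange = "integer"
  ),
  prototype(
    keyId = "key", nTaxa = NA_integer_, nCouplets = NA_integer_,
    nCoupletsExpected = NA_integer_, sActual = NA_real_, sMax = NA_real_,
    sMin = NA_real_, q = NA_integer_, x = NA_integer_, isMaxFan = NA,
    depthRange = c(NA_integer_, NA_integer_)
  )
)

#' RubricResult: verdicts against the 17-criterion suboptimality rubric
#'
#' @slot keyId Identifier of the scored key.
#' @slot verdicts Named character vector, names "c1".."c17", values
#'   "optimal", "suboptimal", or "not-applicable".
#' @slot evidence Named character vector parallel to \code{verdicts}: the
#'   defect category or metadata field that decided each verdict (audit trail).
#' @slot nSuboptimal Count of suboptimal verdicts.
#' @slot nApplicable 17 minus the count of not-applicable verdicts.
#' @slot pctSuboptimal 100 * nSuboptimal / nApplicable.
#' @exportClass RubricResult
setClass("RubricResult",
  representation(
    keyId = "character", verdicts = "character", evidence = "character",
    nSuboptimal = "integer", nApplicable = "integer",
    pctSuboptimal = "numeric"
  )
)

setValidity("RubricResult", function(object) {
  msgs <- character()
  if (length(object@verdicts) != 17L ||
      !identical(names(object@verdicts), paste0("c", 1:17)))
    msgs <- c(msgs, "verdicts must be named c1..c17")
  if (!all(object@verdicts %in% c("optimal", "suboptimal", "not-applicable")))
    msgs <- c(msgs, "invalid verdict value")
  nSub <- sum(object@verdicts == "suboptimal")
  nApp <- 17L - sum(object@verdicts == "not-applicable")
  if (!identical(object@nSuboptimal, nSub))
    msgs <- c(msgs, "nSuboptimal inconsistent with verdicts")
  if (!identical(object@nApplicable, nApp))
    msgs <- c(msgs, "nApplicable inconsistent with verdicts")
  if (nApp >= 1L &&
      abs(object@pctSuboptimal - 100 * nSub / nApp) > 1e-9)
    msgs <- c(msgs, "pctSuboptimal inconsistent with counts")
  if (length(msgs)) msgs else TRUE
})
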