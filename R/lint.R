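#' @include metrics.R
NULL

#' Ambiguity lexicon
#'
#' Word lists driving the wording detectors. Qualifier words ("usually",
#' "often", "normal", ...) make a feature fail whenever the specimen at hand
#' is not of the usual phenotype. Relative markers ("strongly", "weakly",
#' ...) and bare comparatives ("wider", "longer", ...) are comparisons that
#' require elaboration unless an explicit ratio, measurement, or a
#' "...er than ..." construction accompanies them. Matching is
#' case-insensitive on word boundaries.
#'
#' @param qualifierWords,relativeMarkers,bareComparatives Character vectors
#'   overriding the defaults.
#' @return Named list with the three vectors.
#' @export
ambiguityLexicon <- function(
    qualifierWords = c("usually", "often", "normally", "normal",
                       "sometimes", "typically", "mostly", "rarely",
                       "generally"),
    relativeMarkers = c("strongly", "weakly", "relatively", "comparatively",
                        "slightly", "distinctly"),
    bareComparatives = c("wider", "narrower", "longer", "shorter",
                         "larger", "smaller")) {
  stopifnot(length(qualifierWords) > 0, length(relativeMarkers) > 0)
  list(qualifierWords = qualifierWords, relativeMarkers = relativeMarkers,
       bareComparatives = bareComparatives)
}

wordHit <- function(text, words) {
  pat <- paste0("(?i)\\b(", paste(words, collapse = "|"), ")\\b")
  grepl(pat, text, perl = TRUE)
}

# does the feature carry an explicit measurement or ratio ("9-12 mm",
# "2x ocellar diameter", "0.5 times")?
hasMeasurement <- function(text) {
  grepl("[0-9]+(\\.[0-9]+)?\\s*(mm|cm|µm|um|×|x\\b|times\\b|:)",
        text, perl = TRUE, ignore.case = TRUE)
}

#' Detect leap-frog couplets
#'
#' A leap-frog couplet sends the user to a distant couplet from its first
#' lead while the second lead continues to the immediately following couplet
#' number -- the reverse of standard practice, and an invitation to user
#' error. Only couplets whose two leads both reference couplets are
#' considered.
#'
#' @param key A \linkS4class{Key}.
#' @return Defect data.frame (category "leap-frog").
#' @export
detectLeapfrog <- function(key) {
  out <- emptyDefects()
  for (cp in key@couplets) {
    if (length(cp@leads) != 2L) next
    t1 <- cp@leads[[1]]@targetCouplet
    t2 <- cp@leads[[2]]@targetCouplet
    if (is.na(t1) || is.na(t2)) next
    if (t2 == cp@number + 1L && t1 != cp@number + 1L)
      out <- bindDefects(out, defect("leap-frog", couplet = cp@number,
        message = sprintf(
          "first lead jumps to couplet %d while second continues to %d",
          t1, t2)))
  }
  out
}

#' Assess retracing support
#'
#' Retracing is the "N(M)" convention recording which couplet led to the
#' current one, letting a user walk backward out of a dead end. By default a
#' key supports retracing if every non-root couplet that does not simply
#' continue from the couplet immediately above it carries a retrace
#' reference; in strict mode every non-root couplet must carry one. A
#' retrace reference naming a couplet whose leads do not actually target the
#' current one is reported as a numbering error. Keys with two or fewer
#' couplets return NA support (retracing is not relevant to them).
#'
#' @param key A \linkS4class{Key}.
#' @param graph Optional precomputed \linkS4class{KeyGraph}.
#' @param strict Require a reference on every non-root couplet.
#' @return List with \code{supportsRetracing} (logical, NA when not
#'   applicable) and \code{defects} (mismatched references).
#' @export
detectRetracing <- function(key, graph = buildKeyGraph(key),
                            strict = FALSE) {
  defects <- emptyDefects()
  nums <- vapply(key@couplets, coupletNumber, integer(1))
  byNum <- split(key@couplets, nums)
  for (cp in key@couplets) {
    if (is.na(cp@retraceRef)) next
    ref <- cp@retraceRef
    ok <- FALSE
    if (as.character(ref) %in% names(byNum)) {
      for (parent in byNum[[as.character(ref)]])
        for (ld in parent@leads)
          if (!is.na(ld@targetCouplet) && ld@targetCouplet == cp@number)
            ok <- TRUE
    }
    if (!ok)
      defects <- bindDefects(defects, defect("numbering-error",
        couplet = cp@number,
        message = sprintf(
          "retrace reference (%d) but no lead of couplet %d targets %d",
          ref, ref, cp@number)))
  }
  if (length(key@couplets) <= 2L)
    return(list(supportsRetracing = NA, defects = defects))

  par <- graph@parents
  supports <- TRUE
  for (cp in key@couplets) {
    if (cp@number == graph@root) next
    rows <- par[par$couplet == cp@number, , drop = FALSE]
    continues <- nrow(rows) > 0 &&
      any(rows$parentCouplet == cp@number - 1L)
    needed <- if (strict) TRUE else !continues
    if (needed && is.na(cp@retraceRef)) supports <- FALSE
  }
  list(supportsRetracing = supports, defects = defects)
}

#' Detect numbering errors
#'
#' Flags duplicate couplet numbers, gaps in the 1..max sequence, and leads
#' that target one of their own ancestors (a cycle).
#'
#' @param key A \linkS4class{Key}.
#' @return Defect data.frame (categories "numbering-error",
#'   "missing-numbers").
#' @export
detectNumberingErrors <- function(key) {
  out <- numberingChecks(key)
  # cycles: walk from the root; a target already on the current path is a
  # backward reference
  nums <- vapply(key@couplets, coupletNumber, integer(1))
  byNum <- split(seq_along(key@couplets), nums)
  g <- buildKeyGraph(key)
  seenCycle <- new.env()
  walk <- function(num, stack) {
    cp <- key@couplets[[byNum[[as.character(num)]][1]]]
    for (ld in cp@leads) {
      tc <- ld@targetCouplet
      if (is.na(tc) || !tc %in% nums) next
      if (tc %in% c(stack, num)) {
        id <- paste(num, ld@ordinal)
        if (is.null(seenCycle[[id]])) {
          seenCycle[[id]] <- TRUE
          out <<- bindDefects(out, defect("numbering-error",
            couplet = cp@number, lead = ld@ordinal,
            message = sprintf("lead targets couplet %d, an ancestor (cycle)",
                              tc)))
        }
      } else {
        walk(tc, c(stack, num))
      }
    }
  }
  walk(g@root, integer())
  out
}

#' Detect monothetic couplets
#'
#' A monothetic couplet relies on a single feature in both leads: it fails
#' entirely if that structure is missing or obscured on the specimen.
#'
#' @param key A \linkS4class{Key}.
#' @param graph Optional precomputed \linkS4class{KeyGraph}.
#' @return List: \code{perCouplet} (named logical by couplet number),
#'   \code{proportion} (monothetic couplets / all couplets),
#'   \code{allPathsHit} (TRUE iff every taxon's path crosses at least one
#'   monothetic couplet), and \code{defects} (one "monothetic-couplet" record
#'   per monothetic couplet).
#' @export
detectMonothetic <- function(key, graph = buildKeyGraph(key)) {
  per <- vapply(key@couplets, function(cp)
    all(vapply(cp@leads, function(ld) length(ld@features) == 1L,
               logical(1))), logical(1))
  names(per) <- vapply(key@couplets, function(cp)
    as.character(cp@number), character(1))
  defects <- emptyDefects()
  for (cp in key@couplets[per])
    defects <- bindDefects(defects, defect("monothetic-couplet",
      couplet = cp@number,
      message = sprintf("couplet %d uses a single feature in every lead",
                        cp@number)))

  # does every taxon path cross a monothetic couplet?
  monoNums <- as.integer(names(per)[per])
  nums <- vapply(key@couplets, coupletNumber, integer(1))
  byNum <- split(seq_along(key@couplets), nums)
  hitAll <- TRUE
  anyPath <- FALSE
  walk <- function(num, hit, stack) {
    if (num %in% stack) return(invisible(NULL))
    cp <- key@couplets[[byNum[[as.character(num)]][1]]]
    hit <- hit || num %in% monoNums
    for (ld in cp@leads) {
      if (!is.na(ld@targetTaxon)) {
        anyPath <<- TRUE
        if (!hit) hitAll <<- FALSE
      } else if (!is.na(ld@targetCouplet) && ld@targetCouplet %in% nums) {
        walk(ld@targetCouplet, hit, c(stack, num))
      }
    }
  }
  walk(graph@root, FALSE, integer())
  list(perCouplet = per,
       proportion = mean(per),
       allPathsHit = anyPath && hitAll,
       defects = defects)
}

# stoplist skipped when looking for the subject token of a feature
SUBJECT_STOPLIST <- c("the", "a", "an", "with", "without", "of", "in", "on",
                      "at", "and", "or", "not", "no", "its", "their",
                      "usually", "often", "normally", "sometimes",
                      "typically", "mostly", "rarely", "generally",
                      "strongly", "weakly", "relatively", "comparatively",
                      "slightly", "distinctly")

subjectToken <- function(feature) {
  toks <- tolower(strsplit(trimws(feature), "[^A-Za-z0-9µ×._-]+")[[1]])
  toks <- toks[nzchar(toks)]
  toks <- toks[!toks %in% SUBJECT_STOPLIST]
  if (length(toks)) toks[1] else NA_character_
}

#' Detect non-parallel and uncontrasted features in a couplet
#'
#' Features are paired across the two leads by a shallow subject rule: the
#' first content word of each feature (a configurable stoplist removes
#' articles, prepositions, and hedging adverbs). A feature with no partner in
#' the sibling lead is uncontrasted -- the comparison it invites is
#' impossible. Paired features appearing in a different order across the two
#' leads are non-parallel. A couplet whose leads share no paired feature at
#' all is reported as uncontrasted at the couplet level, since no comparison
#' whatsoever is possible.
#'
#' @param couplet A dichotomous \linkS4class{Couplet}.
#' @return Defect data.frame (categories "uncontrasted-feature",
#'   "non-parallel-features").
#' @export
detectParallelContrast <- function(couplet) {
  out <- emptyDefects()
  if (length(couplet@leads) < 2L) return(out)
  f1 <- couplet@leads[[1]]@features
  f2 <- couplet@leads[[2]]@features
  s1 <- vapply(f1, subjectToken, character(1))
  s2 <- vapply(f2, subjectToken, character(1))
  shared <- intersect(s1[!is.na(s1)], s2[!is.na(s2)])

  if (!length(shared)) {
    return(bindDefects(out, defect("uncontrasted-feature",
      couplet = couplet@number,
      message = sprintf(
        "couplet %d: no feature in one lead is contrasted in the other",
        couplet@number))))
  }
  for (i in which(!s1 %in% shared))
    out <- bindDefects(out, defect("uncontrasted-feature",
      couplet = couplet@number, lead = 1L,
      message = sprintf("feature '%s' has no contrast in the second lead",
                        f1[i])))
  for (i in which(!s2 %in% shared))
    out <- bindDefects(out, defect("uncontrasted-feature",
      couplet = couplet@number, lead = 2L,
      message = sprintf("feature '%s' has no contrast in the first lead",
                        f2[i])))
  o1 <- match(shared, s1)
  o2 <- match(shared, s2)
  if (!identical(order(o1), order(o2)))
    out <- bindDefects(out, defect("non-parallel-features",
      couplet = couplet@number,
      message = sprintf(
        "couplet %d treats shared features in a different order in each lead",
        couplet@number)))
  out
}

# parse "9-12 mm" style numeric ranges out of a feature; returns data.frame
# subject, lo, hi (possibly 0 rows)
featureRanges <- function(feature) {
  m <- regmatches(feature, gregexpr(
    "([0-9]+(\\.[0-9]+)?)\\s*[–-]\\s*([0-9]+(\\.[0-9]+)?)",
    feature, perl = TRUE))[[1]]
  if (!length(m)) return(NULL)
  parts <- strsplit(m, "\\s*[–-]\\s*", perl = TRUE)
  data.frame(subject = subjectToken(feature),
             lo = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
             hi = vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
             stringsAsFactors = FALSE)
}

#' Detect ambiguous (indecisive) wording in a couplet
#'
#' A feature is flagged indecisive when it contains a hedging qualifier word,
#' a relative marker or bare comparative with no accompanying measurement,
#' ratio, "...er than" construction, or figure reference, or when numeric
#' ranges for the same measurement in the two leads overlap. Relative and
#' overlapping-range flags are considered resolved -- and dropped -- when both
#' leads of the couplet carry a figure reference, since an illustration of
#' both alternatives settles the comparison; a hedging qualifier cannot be
#' fixed by a figure and is always reported. A couplet in which every
#' feature of at least one lead is flagged (and not resolved) is entirely
#' indecisive.
#'
#' @param couplet A dichotomous \linkS4class{Couplet}.
#' @param lexicon Word lists from \code{\link{ambiguityLexicon}}.
#' @return Defect data.frame (categories "indecisive-feature",
#'   "unresolved-relative-statement", "fully-indecisive-couplet").
#' @export
detectAmbiguity <- function(couplet, lexicon = ambiguityLexicon()) {
  out <- emptyDefects()
  nl <- length(couplet@leads)
  if (nl < 2L) return(out)
  bothIllustrated <- all(vapply(couplet@leads[1:2], function(ld)
    length(ld@figureRefs) > 0, logical(1)))

  flags <- vector("list", nl)  # per lead: logical per feature
  for (li in 1:2) {
    ld <- couplet@leads[[li]]
    fl <- logical(length(ld@features))
    for (fi in seq_along(ld@features)) {
      f <- ld@features[fi]
      qualifier <- wordHit(f, lexicon$qualifierWords)
      relative <- (wordHit(f, lexicon$relativeMarkers) ||
        (wordHit(f, lexicon$bareComparatives) &&
           !grepl("(?i)\\b(wider|narrower|longer|shorter|larger|smaller)\\s+than\\b",
                  f, perl = TRUE))) &&
        !hasMeasurement(f) &&
        !grepl(FIG_PATTERN, f, perl = TRUE)
      if (qualifier) {
        fl[fi] <- TRUE
        out <- bindDefects(out, defect("indecisive-feature",
          couplet = couplet@number, lead = li,
          message = sprintf("qualifier word in feature '%s'", f)))
      }
      if (relative && !bothIllustrated) {
        fl[fi] <- TRUE
        out <- bindDefects(out, defect("unresolved-relative-statement",
          couplet = couplet@number, lead = li,
          message = sprintf("relative statement without measurement: '%s'", f)))
      }
    }
    flags[[li]] <- fl
  }

  # overlapping numeric ranges for the same measurement across leads
  r1 <- do.call(rbind, lapply(couplet@leads[[1]]@features, featureRanges))
  r2 <- do.call(rbind, lapply(couplet@leads[[2]]@features, featureRanges))
  if (!is.null(r1) && !is.null(r2) && !bothIllustrated) {
    for (i in seq_len(nrow(r1))) for (j in seq_len(nrow(r2))) {
      if (!is.na(r1$subject[i]) && identical(r1$subject[i], r2$subject[j]) &&
          r1$lo[i] <= r2$hi[j] && r2$lo[j] <= r1$hi[i]) {
        out <- bindDefects(out, defect("indecisive-feature",
          couplet = couplet@number,
          message = sprintf(
            "ranges %g-%g and %g-%g for '%s' overlap between the leads",
            r1$lo[i], r1$hi[i], r2$lo[j], r2$hi[j], r1$subject[i])))
        # mark the features carrying the overlapping ranges
        for (li in 1:2) {
          rr <- if (li == 1) r1[i, ] else r2[j, ]
          ld <- couplet@leads[[li]]
          hit <- vapply(ld@features, function(f)
            identical(subjectToken(f), rr$subject) &&
              grepl("[0-9]+(\\.[0-9]+)?\\s*[–-]", f, perl = TRUE),
            logical(1))
          flags[[li]][hit] <- TRUE
        }
      }
    }
  }

  fully <- any(vapply(1:2, function(li) all(flags[[li]]) &&
                        length(flags[[li]]) > 0, logical(1)))
  if (fully)
    out <- bindDefects(out, defect("fully-indecisive-couplet",
      couplet = couplet@number,
      message = sprintf(
        "every feature of at least one lead of couplet %d is indecisive",
        couplet@number)))
  out
}

#' Illustration coverage of a key
#'
#' @param key A \linkS4class{Key}.
#' @return List: \code{propLeadsIllustrated} (leads citing at least one
#'   figure / all leads), \code{coverageClass} ("none", "partial", or
#'   "all-leads"), and \code{defects} (one "unillustrated-lead" record per
#'   lead with no figure citation).
#' @export
detectIllustrationCoverage <- function(key) {
  nLeads <- 0L
  nIll <- 0L
  defects <- emptyDefects()
  for (cp in key@couplets) for (ld in cp@leads) {
    nLeads <- nLeads + 1L
    if (length(ld@figureRefs) > 0) nIll <- nIll + 1L
    else defects <- bindDefects(defects, defect("unillustrated-lead",
      couplet = cp@number, lead = ld@ordinal,
      message = sprintf("lead %d of couplet %d cites no figure",
                        ld@ordinal, cp@number)))
  }
  prop <- if (nLeads) nIll / nLeads else 0
  cls <- if (prop == 0) "none" else if (prop == 1) "all-leads" else "partial"
  list(propLeadsIllustrated = prop, coverageClass = cls, defects = defects)
}

#' Detect style-level structural defects
#'
#' Emits yoked-style, polychotomy, looped, duplicate-taxon (informational),
#' and multi-taxon-lead defects from the parsed structure and the key graph.
#'
#' @param key A \linkS4class{Key}.
#' @param graph Optional precomputed \linkS4class{KeyGraph}.
#' @return Defect data.frame.
#' @export
detectStyle <- function(key, graph = buildKeyGraph(key)) {
  out <- emptyDefects()
  if (key@style == "yoked")
    out <- bindDefects(out, defect("yoked-style",
      message = "key is in the yoked style"))
  for (cp in key@couplets) {
    if (length(cp@leads) > 2L)
      out <- bindDefects(out, defect("polychotomy", couplet = cp@number,
        message = sprintf("couplet %d offers %d leads", cp@number,
                          length(cp@leads))))
    for (ld in cp@leads)
      if (!is.na(ld@targetTaxon) &&
          grepl("\\s(and|&)\\s", ld@targetTaxon))
        out <- bindDefects(out, defect("multi-taxon-lead",
          couplet = cp@number, lead = ld@ordinal,
          message = sprintf("more than one taxon keys out in '%s'",
                            ld@targetTaxon)))
  }
  out <- bindDefects(out,
    graph@defects[graph@defects$category == "looped", , drop = FALSE])
  for (nm in names(graph@taxonPaths))
    if (length(graph@taxonPaths[[nm]]) > 1L)
      out <- bindDefects(out, defect("duplicate-taxon",
        message = sprintf("taxon '%s' keys out %d times",
                          graph@taxonLabels[[nm]],
                          length(graph@taxonPaths[[nm]]))))
  out
}

#' Run every detector over a key
#'
#' Aggregates all structural and wording detectors into a single defect
#' table; purely deterministic (identical keys give identical tables).
#'
#' @param key A \linkS4class{Key}.
#' @param lexicon Word lists from \code{\link{ambiguityLexicon}}.
#' @param graph Optional precomputed \linkS4class{KeyGraph}.
#' @return Defect data.frame combining all categories, plus attributes
#'   \code{retracing} (from \code{\link{detectRetracing}}),
#'   \code{monothetic} (from \code{\link{detectMonothetic}}), and
#'   \code{illustration} (from \code{\link{detectIllustrationCoverage}}).
#' @export
lintKey <- function(key, lexicon = ambiguityLexicon(),
                    graph = buildKeyGraph(key)) {
  retr <- detectRetracing(key, graph)
  mono <- detectMonothetic(key, graph)
  ill <- detectIllustrationCoverage(key)
  perCouplet <- lapply(key@couplets, function(cp) {
    if (length(cp@leads) == 2L)
      bindDefects(detectParallelContrast(cp), detectAmbiguity(cp, lexicon))
    else emptyDefects()
  })
  out <- bindDefects(
    validateKey(key),
    detectNumberingErrors(key),
    detectLeapfrog(key),
    detectStyle(key, graph),
    mono$defects,
    retr$defects,
    do.call(bindDefects, perCouplet))
  if (!is.na(retr$supportsRetracing) && !retr$supportsRetracing)
    out <- bindDefects(out, defect("no-retracing",
      message = "key does not state which couplet leads to the current one"))
  out <- unique(out)
  rownames(out) <- NULL
  attr(out, "retracing") <- retr
  attr(out, "monothetic") <- mono
  attr(out, "illustration") <- ill
  out
}
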