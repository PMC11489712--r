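#' @include AllGenerics.R
NULL

# ---- constructors -----------------------------------------------------------

#' Construct a Lead
#'
#' @param features Character vector of discriminating features (non-empty).
#' @param target Either an integer couplet number or a taxon name string; a
#'   character string consisting only of digits is taken as a couplet number.
#' @param ordinal Position of the lead within its couplet.
#' @param figureRefs Character vector of figure citations.
#' @param ancillary Optional ancillary text (NA when absent).
#' @return A \linkS4class{Lead}.
#' @examples
#' Lead("Wings present", target = "Genus_A")
#' Lead(c("Head longer than wide", "hind tibia with spines"), target = 9L)
#' @export
Lead <- function(features, target, ordinal = 1L, figureRefs = character(),
                 ancillary = NA_character_) {
  tc <- NA_integer_
  tt <- NA_character_
  if (is.numeric(target)) {
    tc <- as.integer(target)
  } else if (grepl("^[0-9]+$", target)) {
    tc <- as.integer(target)
  } else {
    tt <- as.character(target)
  }
  new("Lead", ordinal = as.integer(ordinal),
      features = as.character(features), targetCouplet = tc,
      targetTaxon = tt, figureRefs = as.character(figureRefs),
      ancillary = as.character(ancillary))
}

#' Construct a Couplet
#'
#' @param number Printed couplet number.
#' @param leads List of \linkS4class{Lead} objects (ordinals are reassigned
#'   to printed order).
#' @param retraceRef Number of the couplet that led here, or NA.
#' @return A \linkS4class{Couplet}.
#' @export
Couplet <- function(number, leads, retraceRef = NA_integer_) {
  leads <- lapply(seq_along(leads), function(i) {
    ld <- leads[[i]]
    ld@ordinal <- i
    ld
  })
  new("Couplet", number = as.integer(number),
      retraceRef = as.integer(retraceRef), leads = leads)
}

#' Construct a Key
#'
#' @param couplets List of \linkS4class{Couplet} objects in printed order.
#' @param keyId Identifier string.
#' @param title Printed title ("" when absent).
#' @param scope Named list; missing entries are filled with defaults
#'   (\code{rank}, \code{extent}, \code{sex}, \code{caste} default NA,
#'   \code{isEmendation} FALSE).
#' @param style Key style; by default inferred from the leads: any couplet
#'   with more than two leads makes the key "mixed-polychotomous".
#' @return A \linkS4class{Key}.
#' @export
Key <- function(couplets, keyId = "key", title = "", scope = list(),
                style = NULL) {
  defaults <- list(rank = NA_character_, extent = NA_character_,
                   sex = NA_character_, caste = NA_character_,
                   isEmendation = FALSE)
  defaults[names(scope)] <- scope
  if (is.null(style)) {
    poly <- any(vapply(couplets, function(cp) length(cp@leads) > 2L,
                       logical(1)))
    style <- if (poly) "mixed-polychotomous" else "dichotomous"
  }
  new("Key", keyId = as.character(keyId), title = as.character(title),
      scope = defaults, couplets = couplets, style = style)
}

# ---- accessors --------------------------------------------------------------

#' @rdname key-accessors
setMethod("keyId", "Key", function(x) x@keyId)
#' @rdname key-accessors
setMethod("keyId", "KeyMetrics", function(x) x@keyId)
#' @rdname key-accessors
setMethod("keyId", "RubricResult", function(x) x@keyId)
#' @rdname key-accessors
setMethod("keyTitle", "Key", function(x) x@title)
#' @rdname key-accessors
setMethod("keyStyle", "Key", function(x) x@style)
#' @rdname key-accessors
setMethod("keyScope", "Key", function(x) x@scope)
#' @rdname key-accessors
setMethod("couplets", "Key", function(x) x@couplets)
#' @rdname key-accessors
setMethod("coupletNumber", "Couplet", function(x) x@number)
#' @rdname key-accessors
setMethod("retraceRef", "Couplet", function(x) x@retraceRef)
#' @rdname key-accessors
setMethod("leads", "Couplet", function(x) x@leads)
#' @rdname key-accessors
setMethod("leadFeatures", "Lead", function(x) x@features)
#' @rdname key-accessors
setMethod("figureRefs", "Lead", function(x) x@figureRefs)

#' @rdname key-accessors
#' @details \code{leadTarget} returns the couplet number (integer) or the
#'   taxon name (character), whichever is set.
setMethod("leadTarget", "Lead", function(x) {
  if (!is.na(x@targetCouplet)) x@targetCouplet else x@targetTaxon
})

setMethod("verdicts", "RubricResult", function(x) x@verdicts)
setMethod("nSuboptimal", "RubricResult", function(x) x@nSuboptimal)
setMethod("nApplicable", "RubricResult", function(x) x@nApplicable)
setMethod("pctSuboptimal", "RubricResult", function(x) x@pctSuboptimal)

#' Normalize a taxon name for identity comparison
#'
#' Identity is exact string match after whitespace squeezing and case folding;
#' a taxon keying out more than once is one taxon with multiple paths.
#'
#' @param x Character vector of names.
#' @return Normalized names.
#' @export
normalizeTaxon <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

setMethod("keyTaxa", "Key", function(x) {
  nm <- character()
  seen <- character()
  for (cp in x@couplets) for (ld in cp@leads) {
    if (!is.na(ld@targetTaxon)) {
      key <- normalizeTaxon(ld@targetTaxon)
      if (!key %in% seen) {
        seen <- c(seen, key)
        nm <- c(nm, ld@targetTaxon)
      }
    }
  }
  nm
})

# ---- defect tables ----------------------------------------------------------

#' Defect records
#'
#' Defects are data, not exceptions: every detector returns a data.frame with
#' columns \code{category} (from \code{\link{defectCategories}}),
#' \code{couplet}, \code{lead} (NA when not tied to a locus), and
#' \code{message}.
#'
#' @param category Defect category (must be in the closed vocabulary).
#' @param couplet,lead Optional integer locus.
#' @param message Human-readable explanation.
#' @return One-row (or zero-row, for \code{emptyDefects}) defect data.frame.
#' @export
defect <- function(category, couplet = NA_integer_, lead = NA_integer_,
                   message = "") {
  stopifnot(category %in% defectCategories())
  data.frame(category = category, couplet = as.integer(couplet),
             lead = as.integer(lead), message = message,
             stringsAsFactors = FALSE)
}

#' @rdname defect
#' @export
emptyDefects <- function() {
  data.frame(category = character(), couplet = integer(), lead = integer(),
             message = character(), stringsAsFactors = FALSE)
}

bindDefects <- function(...) {
  xs <- Filter(function(d) is.data.frame(d) && nrow(d) > 0, list(...))
  if (!length(xs)) return(emptyDefects())
  do.call(rbind, c(list(emptyDefects()), xs))
}

# ---- representation-level validation ---------------------------------------

#' Structural well-formedness check
#'
#' Reports representation-level violations -- duplicate couplet numbers and
#' couplet targets that refer to no couplet in the key -- as defect records
#' without raising. An empty result means graph construction may proceed
#' safely.
#'
#' @param key A \linkS4class{Key}.
#' @return Defect data.frame (categories numbering-error, dangling-reference).
#' @export
validateKey <- function(key) {
  nums <- vapply(key@couplets, coupletNumber, integer(1))
  out <- emptyDefects()
  dup <- unique(nums[duplicated(nums)])
  for (d in dup)
    out <- bindDefects(out, defect("numbering-error", couplet = d,
      message = sprintf("couplet number %d is used more than once", d)))
  for (cp in key@couplets) for (ld in cp@leads) {
    if (!is.na(ld@targetCouplet) && !ld@targetCouplet %in% nums)
      out <- bindDefects(out, defect("dangling-reference",
        couplet = cp@number, lead = ld@ordinal,
        message = sprintf("lead targets couplet %d which is not in the key",
                          ld@targetCouplet)))
  }
  out
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "Key", function(object) {
  nTax <- length(keyTaxa(object))
  cat(sprintf("Key '%s' (%s): %d couplets, %d taxa\n", object@keyId,
              object@style, length(object@couplets), nTax))
  if (nzchar(object@title)) cat("  title:", object@title, "\n")
  invisible(NULL)
})

setMethod("show", "Couplet", function(object) {
  hdr <- if (is.na(object@retraceRef)) sprintf("%d", object@number)
         else sprintf("%d(%d)", object@number, object@retraceRef)
  cat(sprintf("Couplet %s with %d leads\n", hdr, length(object@leads)))
  invisible(NULL)
})

setMethod("show", "KeyMetrics", function(object) {
  cat(sprintf("KeyMetrics for '%s'\n", object@keyId))
  cat(sprintf("  taxa: %d  couplets: %d (expected %d)\n", object@nTaxa,
              object@nCouplets, object@nCoupletsExpected))
  cat(sprintf("  mean steps: %.4f  [fan min %.4f, comb max %.4f]\n",
              object@sActual, object@sMin, object@sMax))
  cat(sprintf("  depth range: %d..%d  maximally fan-shaped: %s\n",
              object@depthRange[1], object@depthRange[2],
              ifelse(is.na(object@isMaxFan), "NA", object@isMaxFan)))
  invisible(NULL)
})

setMethod("show", "RubricResult", function(object) {
  cat(sprintf("RubricResult for '%s': %d/%d criteria suboptimal (%.1f%%)\n",
              object@keyId, object@nSuboptimal, object@nApplicable,
              object@pctSuboptimal))
  invisible(NULL)
})

setMethod("show", "ParseReport", function(object) {
  cat(sprintf("ParseReport: %d couplets, %d warnings, %d unparsed lines\n",
              length(object@key@couplets), nrow(object@warnings),
              nrow(object@unparsedLines)))
  invisible(NULL)
})

# ---- structural equality and serialization ---------------------------------

leadAsList <- function(ld) {
  list(ordinal = ld@ordinal, features = as.list(ld@features),
       targetCouplet = ld@targetCouplet, targetTaxon = ld@targetTaxon,
       figureRefs = as.list(ld@figureRefs), ancillary = ld@ancillary)
}

coupletAsList <- function(cp) {
  list(number = cp@number, retraceRef = cp@retraceRef,
       leads = lapply(cp@leads, leadAsList))
}

#' Plain-list form of a Key
#'
#' Used for structural equality testing and JSON serialization.
#'
#' @param key A \linkS4class{Key}.
#' @return Nested named list mirroring the object structure.
#' @export
keyAsList <- function(key) {
  list(keyId = key@keyId, title = key@title, scope = key@scope,
       style = key@style, couplets = lapply(key@couplets, coupletAsList))
}

#' Structural equality of two keys
#'
#' Compares everything canonical text carries: title, style, and the full
#' couplet/lead structure (features, targets, retrace and figure references,
#' ancillary text). Identifier and scope metadata, which have no printed
#' form, are not compared.
#'
#' @param a,b \linkS4class{Key} objects.
#' @return TRUE iff the two keys are structurally identical.
#' @export
keysEqual <- function(a, b) {
  structure_ <- function(k)
    list(title = k@title, style = k@style,
         couplets = lapply(k@couplets, coupletAsList))
  identical(structure_(a), structure_(b))
}

#' Serialize a Key to JSON and back
#'
#' @param key A \linkS4class{Key}.
#' @param json JSON text produced by \code{keyToJSON}.
#' @return \code{keyToJSON}: a JSON string; \code{keyFromJSON}: a Key.
#' @export
keyToJSON <- function(key) {
  jsonlite::toJSON(keyAsList(key), auto_unbox = TRUE, null = "null",
                   na = "null", digits = NA)
}

#' @rdname keyToJSON
#' @export
keyFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  asNAint <- function(v) if (is.null(v)) NA_integer_ else as.integer(v)
  asNAchr <- function(v) if (is.null(v)) NA_character_ else as.character(v)
  cps <- lapply(x$couplets, function(cp) {
    lds <- lapply(cp$leads, function(ld) {
      tc <- asNAint(ld$targetCouplet)
      tgt <- if (!is.na(tc)) tc else asNAchr(ld$targetTaxon)
      Lead(features = unlist(ld$features), target = tgt,
           ordinal = ld$ordinal,
           figureRefs = as.character(unlist(ld$figureRefs)),
           ancillary = asNAchr(ld$ancillary))
    })
    Couplet(cp$number, lds, retraceRef = asNAint(cp$retraceRef))
  })
  sc <- x$scope
  sc <- lapply(sc, function(v) if (is.null(v)) NA else v)
  Key(cps, keyId = x$keyId, title = x$title, scope = sc, style = x$style)
}

#' Export metrics as a one-row data.frame
#'
#' Column names match the KeyMetrics fields so rows from many keys can be
#' stacked into a corpus table and written to CSV.
#'
#' @param m A \linkS4class{KeyMetrics}.
#' @return One-row data.frame.
#' @export
metricsAsRow <- function(m) {
  data.frame(keyId = m@keyId, nTaxa = m@nTaxa, nCouplets = m@nCouplets,
             nCoupletsExpected = m@nCoupletsExpected, sActual = m@sActual,
             sMin = m@sMin, sMax = m@sMax, q = m@q, x = m@x,
             isMaxFan = m@isMaxFan, depthMin = m@depthRange[1],
             depthMax = m@depthRange[2], stringsAsFactors = FALSE)
}
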