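#' @include key-graph.R
NULL

# Default pattern for figure citations within a lead.
FIG_PATTERN <- "(?i)\\bfigs?\\.?\\s*[0-9][0-9A-Za-z]*(\\s*[,&–-]\\s*[0-9A-Za-z]+)*"

# Header "N", "N.", "N)", "N(M)", "N(M)."
HEADER_RE <- "^\\s*([0-9]+)\\s*(\\(([0-9]+)\\))?\\s*[.)]?\\s+(.+)$"
# Continuation lead: dash / en dash / em dash
DASH_RE <- "^\\s*[-–—]\\s*(.+)$"
# Continuation lead: repeated couplet number with a prime mark ("3'. ...")
PRIME_RE <- "^\\s*([0-9]+)\\s*['′’]\\s*[.)]?\\s*(.+)$"
# Yoked lead marker: a repeated single letter, "A." / "AA." / "B)" ...
YOKED_RE <- "^\\s*([A-Z])(\\1?)\\s*[.)]\\s+(.+)$"

#' Extract figure citations from lead text
#'
#' @param text Lead body text.
#' @param pattern Perl regex for a citation (default matches "Fig. 3A",
#'   "figs 2, 4", "Fig. 1--3" and similar).
#' @return Character vector of citation strings (possibly empty).
#' @export
extractFigureRefs <- function(text, pattern = FIG_PATTERN) {
  m <- gregexpr(pattern, text, perl = TRUE)
  refs <- regmatches(text, m)[[1]]
  as.character(trimws(refs))
}

# Split a lead body into (features, target, figureRefs, ancillary).
# Returns NULL when no target can be identified.
parseLeadBody <- function(body, figPattern = FIG_PATTERN) {
  body <- trimws(body)
  if (!nzchar(body)) return(NULL)

  target <- NULL
  rest <- body

  m <- regmatches(body, regexec("^(.*\\S)\\s+([0-9]+)\\s*$", body))[[1]]
  if (length(m)) {
    target <- as.integer(m[3])
    rest <- m[2]
  } else {
    # Taxon target: trailing run of name-like tokens ending the line, trimmed
    # forward so it begins at a capitalized token; authors and "and"/"&"
    # joined multi-taxon leads stay inside the run.
    toks <- strsplit(body, "\\s+")[[1]]
    nameLike <- grepl("^[A-Za-z_][A-Za-z0-9_.()&',–-]*$", toks) |
      toks %in% c("and", "&")
    i <- length(toks)
    while (i >= 1 && nameLike[i]) i <- i - 1
    run <- if (i < length(toks)) (i + 1):length(toks) else integer()
    capStart <- run[grepl("^[A-Z_]", toks[run])]
    # walk target start backward over contiguous capitalized/connector tokens
    if (length(capStart)) {
      start <- max(capStart)
      while (start > min(run)) {
        prev <- toks[start - 1]
        if (grepl("^[A-Z_]", prev) || prev %in% c("and", "&"))
          start <- start - 1
        else break
      }
      # never let the target swallow the whole body: a lead needs features
      if (start > 1) {
        target <- paste(toks[start:length(toks)], collapse = " ")
        rest <- paste(toks[1:(start - 1)], collapse = " ")
      }
    }
    if (is.null(target)) return(NULL)
  }

  figureRefs <- extractFigureRefs(rest, figPattern)

  ancillary <- NA_character_
  am <- regmatches(rest,
    regexec("^(.*\\S)\\s*[[(]([^][()]+)[])]\\s*$", rest))[[1]]
  if (length(am) &&
      !grepl(figPattern, am[3], perl = TRUE)) {
    ancillary <- trimws(am[3])
    rest <- am[2]
  }

  features <- trimws(strsplit(rest, ";")[[1]])
  features <- features[nzchar(features)]
  if (!length(features)) return(NULL)

  list(features = features, target = target, figureRefs = figureRefs,
       ancillary = ancillary)
}

# Numbering checks shared by the parser's warning pass and the lint module:
# duplicate printed numbers and gaps in the 1..max sequence.
numberingChecks <- function(key) {
  nums <- vapply(key@couplets, coupletNumber, integer(1))
  out <- emptyDefects()
  for (d in unique(nums[duplicated(nums)]))
    out <- bindDefects(out, defect("numbering-error", couplet = d,
      message = sprintf("duplicated couplet number %d", d)))
  if (length(nums)) {
    missing <- setdiff(seq_len(max(nums)), nums)
    for (g in missing)
      out <- bindDefects(out, defect("missing-numbers", couplet = g,
        message = sprintf("no couplet numbered %d in sequence 1..%d",
                          g, max(nums))))
  }
  out
}

#' Parse plain-text key into a Key object
#'
#' Accepts the conventional numbered-couplet dialect: a couplet opens with a
#' header of the form \code{"N"}, \code{"N."}, or \code{"N(M)"} (the M being
#' the retrace reference to the couplet that led here), with the first lead on
#' the header line; later leads open with a dash (hyphen, en or em dash) or
#' with the couplet number repeated with a prime mark (\code{"3'."}). A
#' trailing integer is a couplet target; a trailing capitalized name
#' (optionally with an author string) is a taxon. Bracketed or parenthesized
#' material immediately before the target that is not a figure citation is
#' captured as ancillary information. Features within a lead are split on
#' semicolons; commas are kept (a comma marks a subordinate clause of one
#' feature, not a new feature). Yoked keys using letter-pair lead markers
#' (\code{"A."} ... \code{"AA."}) are recognized and mapped onto the same
#' couplet model with style "yoked".
#'
#' All lesser problems (polychotomies, duplicate or gappy numbering, yoked
#' style) are returned as warnings in the report; the only hard error is text
#' in which no couplet header is found at all.
#'
#' @param text Key text (single string with newlines, or a character vector
#'   of lines).
#' @param dialectHints Optional list: \code{figPattern} (perl regex for
#'   figure citations), \code{keyId}, \code{scope} (passed to
#'   \code{\link{Key}}).
#' @return A \linkS4class{ParseReport}.
#' @examples
#' rep <- parseKey(c(
#'   "3(2) Head longer than wide; hind tibia with apicoventral spines 9",
#'   "– Head shorter than wide; hind tibia lacking apicoventral spines, surface flat 4"))
#' couplets(rep@key)[[1]]
#' @export
parseKey <- function(text, dialectHints = list()) {
  figPattern <- dialectHints$figPattern %||% FIG_PATTERN
  keyIdHint <- dialectHints$keyId %||% "key"
  scopeHint <- dialectHints$scope %||% list()

  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else as.character(text)
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty input: nothing to parse")

  title <- ""
  unparsed <- data.frame(line = integer(), text = character(),
                         stringsAsFactors = FALSE)
  couplets <- list()        # list of list(number, retraceRef, bodies)
  current <- NULL
  yoked <- FALSE
  yokedIndex <- list()      # letter -> index into couplets

  closeCurrent <- function() {
    if (!is.null(current)) couplets[[length(couplets) + 1L]] <<- current
    current <<- NULL
  }

  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next

    ym <- regmatches(ln, regexec(YOKED_RE, ln))[[1]]
    if (length(ym)) {
      letter <- ym[2]
      doubled <- nzchar(ym[3])
      body <- ym[4]
      yoked <- TRUE
      if (!doubled) {
        closeCurrent()
        couplets[[length(couplets) + 1L]] <- list(
          number = length(couplets) + 1L, retraceRef = NA_integer_,
          bodies = list(body), srcLines = i)
        yokedIndex[[letter]] <- length(couplets)
      } else if (!is.null(yokedIndex[[letter]])) {
        j <- yokedIndex[[letter]]
        couplets[[j]]$bodies <- c(couplets[[j]]$bodies, list(body))
        couplets[[j]]$srcLines <- c(couplets[[j]]$srcLines, i)
      } else {
        unparsed <- rbind(unparsed, data.frame(line = i, text = ln,
                                               stringsAsFactors = FALSE))
      }
      next
    }

    dm <- regmatches(ln, regexec(DASH_RE, ln))[[1]]
    if (length(dm) && !is.null(current)) {
      current$bodies <- c(current$bodies, list(dm[2]))
      current$srcLines <- c(current$srcLines, i)
      next
    }

    pm <- regmatches(ln, regexec(PRIME_RE, ln))[[1]]
    if (length(pm) && !is.null(current)) {
      current$bodies <- c(current$bodies, list(pm[3]))
      current$srcLines <- c(current$srcLines, i)
      next
    }

    hm <- regmatches(ln, regexec(HEADER_RE, ln))[[1]]
    if (length(hm)) {
      closeCurrent()
      current <- list(number = as.integer(hm[2]),
                      retraceRef = if (nzchar(hm[4])) as.integer(hm[4])
                                   else NA_integer_,
                      bodies = list(hm[5]), srcLines = i)
      next
    }

    if (!length(couplets) && is.null(current) && !nzchar(title)) {
      title <- trimws(ln)
    } else {
      unparsed <- rbind(unparsed, data.frame(line = i, text = ln,
                                             stringsAsFactors = FALSE))
    }
  }
  closeCurrent()

  if (!length(couplets))
    stop("no couplet header found: input does not look like an identification key")

  warnings <- emptyDefects()
  built <- list()
  for (cp in couplets) {
    lds <- list()
    for (j in seq_along(cp$bodies)) {
      parsed <- parseLeadBody(cp$bodies[[j]], figPattern)
      if (is.null(parsed)) {
        unparsed <- rbind(unparsed, data.frame(
          line = cp$srcLines[min(j, length(cp$srcLines))],
          text = cp$bodies[[j]], stringsAsFactors = FALSE))
        next
      }
      lds[[length(lds) + 1L]] <- Lead(parsed$features, parsed$target,
        ordinal = length(lds) + 1L, figureRefs = parsed$figureRefs,
        ancillary = parsed$ancillary)
    }
    if (length(lds) < 2L) {
      for (j in seq_along(cp$srcLines))
        unparsed <- rbind(unparsed, data.frame(line = cp$srcLines[j],
          text = cp$bodies[[min(j, length(cp$bodies))]],
          stringsAsFactors = FALSE))
      next
    }
    if (length(lds) > 2L)
      warnings <- bindDefects(warnings, defect("polychotomy",
        couplet = cp$number,
        message = sprintf("couplet %d has %d leads", cp$number, length(lds))))
    built[[length(built) + 1L]] <- Couplet(cp$number, lds,
                                           retraceRef = cp$retraceRef)
  }
  if (!length(built))
    stop("no couplet could be assembled from the input")

  style <- if (yoked) "yoked" else {
    if (any(vapply(built, function(b) length(b@leads) > 2L, logical(1))))
      "mixed-polychotomous" else "dichotomous"
  }
  if (yoked)
    warnings <- bindDefects(warnings,
      defect("yoked-style", message = "key uses yoked letter-pair leads"))

  key <- Key(built, keyId = keyIdHint, title = title, scope = scopeHint,
             style = style)
  warnings <- bindDefects(warnings, numberingChecks(key))
  unparsed <- unparsed[order(unparsed$line), , drop = FALSE]
  rownames(unparsed) <- NULL
  new("ParseReport", key = key, warnings = warnings,
      unparsedLines = unparsed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
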