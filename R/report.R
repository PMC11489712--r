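#' @include synthetic.R
NULL

#' Render a human-readable assessment report
#'
#' Sections: a header with the key's identity and scope, a metrics block
#' comparing the actual mean steps with the fan/comb bounds, a defect table
#' (one line per defect), and the rubric verdict table with its audit trail.
#'
#' @param key A \linkS4class{Key}.
#' @param metrics \linkS4class{KeyMetrics}, or NULL for keys (e.g. isolated
#'   fragments with dangling targets) whose metrics cannot be computed.
#' @param defects Defect data.frame from \code{\link{lintKey}}.
#' @param rubric Optional \linkS4class{RubricResult}.
#' @return List: \code{text} (single report string) and \code{rows}
#'   (data.frame of defect rows suitable for CSV export).
#' @export
renderReport <- function(key, metrics = computeMetrics(key),
                         defects = lintKey(key), rubric = NULL) {
  ln <- character()
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== Key assessment: %s ==", key@keyId)
  if (nzchar(key@title)) add("title: %s", key@title)
  add("style: %s | couplets: %d", key@style, length(key@couplets))
  sc <- key@scope
  add("scope: rank=%s extent=%s sex=%s caste=%s emendation=%s",
      sc$rank, sc$extent, sc$sex, sc$caste, sc$isEmendation)
  add("")
  add("-- Metrics --")
  if (is.null(metrics)) {
    add("metrics unavailable for this key fragment")
  } else {
    add("taxa: %d; couplets observed %d, expected (n-1) %d", metrics@nTaxa,
        metrics@nCouplets, metrics@nCoupletsExpected)
    add("mean steps to identification: %s",
        if (is.na(metrics@sActual)) "NA (looped key)"
        else sprintf("%.4f", metrics@sActual))
    if (!is.na(metrics@sMin))
      add("fan-shaped minimum %.4f, comb-shaped maximum %.4f%s",
          metrics@sMin, metrics@sMax,
          if (isTRUE(metrics@isMaxFan)) " [as fan-shaped as possible]"
          else "")
    else
      add("fan/comb bounds not applicable (non-dichotomous or malformed key)")
    add("path length range: %d..%d", metrics@depthRange[1],
        metrics@depthRange[2])
  }
  add("")
  add("-- Defects --")
  if (nrow(defects) == 0) {
    add("no defects")
  } else {
    for (i in seq_len(nrow(defects)))
      add("%-26s couplet %-4s lead %-2s %s", defects$category[i],
          ifelse(is.na(defects$couplet[i]), "-", defects$couplet[i]),
          ifelse(is.na(defects$lead[i]), "-", defects$lead[i]),
          defects$message[i])
  }
  if (!is.null(rubric)) {
    add("")
    add("-- Rubric (%d/%d applicable criteria suboptimal, %.1f%%) --",
        rubric@nSuboptimal, rubric@nApplicable, rubric@pctSuboptimal)
    for (i in 1:17)
      add("criterion %2d: %-14s %s", i,
          rubric@verdicts[[paste0("c", i)]],
          rubric@evidence[[paste0("c", i)]])
  }
  list(text = paste(ln, collapse = "\n"),
       rows = cbind(data.frame(keyId = rep(key@keyId,
                                           max(1, nrow(defects)))[seq_len(nrow(defects))],
                               stringsAsFactors = FALSE),
                    defects))
}

#' Serialize defects or metrics to JSON
#'
#' @param x A defect data.frame, \linkS4class{KeyMetrics}, or
#'   \linkS4class{RubricResult}.
#' @return JSON string.
#' @export
toReportJSON <- function(x) {
  if (is(x, "KeyMetrics")) x <- metricsAsRow(x)
  if (is(x, "RubricResult")) x <- rubricAsTable(list(x))
  jsonlite::toJSON(x, auto_unbox = FALSE, na = "null", digits = NA,
                   dataframe = "rows")
}
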