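#' @include parser.R
NULL

renderLeadBody <- function(ld) {
  body <- paste(ld@features, collapse = "; ")
  if (!is.na(ld@ancillary) && nzchar(ld@ancillary))
    body <- paste0(body, " [", ld@ancillary, "]")
  tgt <- if (!is.na(ld@targetCouplet)) as.character(ld@targetCouplet)
         else ld@targetTaxon
  paste(body, tgt)
}

#' Render a Key back to canonical plain text
#'
#' The canonical layout: the title (if any) on its own line; each couplet
#' opens with \code{"N"} or \code{"N(M)"} when a retrace reference is set,
#' followed by the first lead; second and later leads are prefixed
#' \code{"– "}; features are joined by \code{"; "}; ancillary text appears in
#' square brackets immediately before the target. Yoked keys are rendered
#' with letter-pair markers (\code{"A."} ... \code{"AA."}).
#'
#' \code{parseKey(renderKey(k))} yields a key structurally equal to \code{k}
#' for any key free of dangling references.
#'
#' @param key A \linkS4class{Key} with no dangling couplet references.
#' @return A single string of key text.
#' @export
renderKey <- function(key) {
  v <- validateKey(key)
  if (any(v$category == "dangling-reference"))
    stop("cannot render a key with dangling couplet references: ",
         paste(unique(v$message[v$category == "dangling-reference"]),
               collapse = "; "))
  out <- character()
  if (nzchar(key@title)) out <- c(out, key@title)
  if (key@style == "yoked") {
    if (length(key@couplets) > 26L)
      stop("yoked rendering supports at most 26 couplets")
    for (i in seq_along(key@couplets)) {
      cp <- key@couplets[[i]]
      if (length(cp@leads) != 2L)
        stop("yoked rendering requires strictly dichotomous couplets")
      letter <- LETTERS[i]
      out <- c(out,
        paste0(letter, ". ", renderLeadBody(cp@leads[[1]])),
        paste0(letter, letter, ". ", renderLeadBody(cp@leads[[2]])))
    }
  } else {
    for (cp in key@couplets) {
      hdr <- if (is.na(cp@retraceRef)) sprintf("%d", cp@number)
             else sprintf("%d(%d)", cp@number, cp@retraceRef)
      out <- c(out, paste(hdr, renderLeadBody(cp@leads[[1]])))
      for (j in 2:length(cp@leads))
        out <- c(out, paste0("– ", renderLeadBody(cp@leads[[j]])))
    }
  }
  paste(out, collapse = "\n")
}
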