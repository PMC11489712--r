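#' @include key-model.R
NULL

#' Build the decision graph over a key
#'
#' Resolves couplet targets into parent/child edges, finds the root couplet,
#' records the path length of every taxon occurrence (couplets traversed from
#' the root, the root itself counting as 1), and reports graph-level defects:
#' a couplet reachable through two different paths is "looped", a couplet with
#' no path from the root is unreachable, and a target naming an absent couplet
#' dangles.
#'
#' When a couplet number is duplicated, traversal follows the first couplet
#' printed with that number; the duplication itself is reported by
#' \code{\link{validateKey}} and \code{\link{detectNumberingErrors}}.
#' Cycles (a lead targeting one of its own ancestors) are cut during
#' traversal so path collection always terminates.
#'
#' @param key A \linkS4class{Key}.
#' @return A \linkS4class{KeyGraph}.
#' @export
buildKeyGraph <- function(key) {
  cps <- key@couplets
  if (!length(cps)) stop("key has no couplets")
  nums <- vapply(cps, coupletNumber, integer(1))
  byNum <- split(seq_along(cps), nums)  # indices by printed number

  edges <- data.frame(couplet = integer(), parentCouplet = integer(),
                      parentLead = integer(), stringsAsFactors = FALSE)
  defects <- emptyDefects()
  for (cp in cps) for (ld in cp@leads) {
    tc <- ld@targetCouplet
    if (is.na(tc)) next
    if (!tc %in% nums) {
      defects <- bindDefects(defects, defect("dangling-reference",
        couplet = cp@number, lead = ld@ordinal,
        message = sprintf("target couplet %d absent from key", tc)))
    } else {
      edges <- rbind(edges, data.frame(couplet = tc,
        parentCouplet = cp@number, parentLead = ld@ordinal,
        stringsAsFactors = FALSE))
    }
  }

  targeted <- unique(edges$couplet)
  rootCandidates <- nums[!nums %in% targeted]
  root <- if (length(rootCandidates)) rootCandidates[1] else nums[1]

  for (n in unique(edges$couplet)) {
    if (sum(edges$couplet == n) > 1L)
      defects <- bindDefects(defects, defect("looped", couplet = n,
        message = sprintf("couplet %d is reachable through %d different paths",
                          n, sum(edges$couplet == n))))
  }

  paths <- list()
  labels <- character()
  reached <- integer()
  visit <- function(num, depth, stack) {
    if (num %in% stack) return(invisible(NULL))  # cycle: cut traversal
    reached <<- union(reached, num)
    cp <- cps[[byNum[[as.character(num)]][1]]]
    for (ld in cp@leads) {
      if (!is.na(ld@targetTaxon)) {
        nm <- normalizeTaxon(ld@targetTaxon)
        if (!nm %in% names(labels)) {
          labels[nm] <<- ld@targetTaxon
          paths[[nm]] <<- integer()
        }
        paths[[nm]] <<- c(paths[[nm]], depth)
      } else if (!is.na(ld@targetCouplet) && ld@targetCouplet %in% nums) {
        visit(ld@targetCouplet, depth + 1L, c(stack, num))
      }
    }
    invisible(NULL)
  }
  visit(root, 1L, integer())

  for (n in setdiff(unique(nums), reached))
    defects <- bindDefects(defects, defect("unreachable-couplet",
      couplet = n, message = sprintf("couplet %d has no path from the root", n)))

  new("KeyGraph", root = as.integer(root), parents = edges,
      taxonPaths = paths, taxonLabels = labels, defects = defects)
}
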