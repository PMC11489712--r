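#' @include renderer.R
NULL

#' Closed-form mean path lengths for comb- and fan-shaped keys
#'
#' For a strictly dichotomous key to \code{n} terminal taxa, the mean number
#' of couplets a user traverses to reach an identification is bounded by two
#' closed forms. The maximally unbalanced (comb-shaped, caterpillar) topology
#' gives the upper bound
#' \deqn{S_{max} = \frac{n+1}{2} - \frac{1}{n}}
#' and the maximally balanced (fan-shaped) topology gives the lower bound
#' \deqn{S_{min} = \frac{Q(2^Q - x) + (Q+1)\,2x}{n}}
#' with \eqn{Q = \lfloor \log_2 n \rfloor} and \eqn{x = n - 2^Q}. When
#' \eqn{x = 0} (n a power of two) the fan bound is exactly \eqn{\log_2 n}.
#' Both forms count the root couplet as step 1.
#'
#' @param n Number of terminal taxa; must be >= 2 (a key needs two taxa).
#' @return Mean path length in couplets.
#' @examples
#' meanStepsComb(16)  # 8.4375, prints as 8.4
#' meanStepsFan(16)   # exactly 4
#' @export
meanStepsComb <- function(n) {
  n <- checkTaxonCount(n)
  (n + 1) / 2 - 1 / n
}

#' @rdname meanStepsComb
#' @export
meanStepsFan <- function(n) {
  n <- checkTaxonCount(n)
  q <- floor(log2(n))
  # guard the floating floor at exact powers of two
  if (2^(q + 1) <= n) q <- q + 1
  x <- n - 2^q
  (q * (2^q - x) + (q + 1) * 2 * x) / n
}

checkTaxonCount <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 2 || n != as.integer(n))
    stop("n must be a single integer >= 2")
  as.numeric(n)
}

#' Path-length metrics for a key
#'
#' Computes the actual mean number of couplets to identification, averaging
#' the occurrences of any taxon that keys out more than once per taxon first,
#' then averaging over taxa. For a strictly dichotomous key with no loops or
#' unreachable couplets the comb/fan closed-form bounds are attached; keys
#' with polychotomies, loops, or unreachable couplets get NA bounds (the
#' closed forms rely on all couplets being dichotomous, so such keys are
#' excluded from the fan/comb comparison). A looped key also gets NA
#' \code{sActual}, since a taxon behind a looped couplet has no single
#' defined path length.
#'
#' @param key A \linkS4class{Key}.
#' @param graph Optionally a precomputed \code{\link{buildKeyGraph}} result.
#' @return A \linkS4class{KeyMetrics}.
#' @export
computeMetrics <- function(key, graph = buildKeyGraph(key)) {
  if (!length(key@couplets)) stop("empty key")
  paths <- graph@taxonPaths
  if (!length(paths)) stop("key resolves to no terminal taxa")
  nTaxa <- length(paths)
  nCouplets <- length(key@couplets)
  perTaxon <- vapply(paths, mean, numeric(1))
  allDepths <- unlist(paths, use.names = FALSE)

  looped <- any(graph@defects$category == "looped")
  unreachable <- any(graph@defects$category == "unreachable-couplet")
  poly <- any(vapply(key@couplets, function(cp) length(cp@leads) != 2L,
                     logical(1)))

  sActual <- if (looped) NA_real_ else mean(perTaxon)
  boundsOK <- !poly && !looped && !unreachable && nTaxa >= 2
  sMax <- if (boundsOK) meanStepsComb(nTaxa) else NA_real_
  sMin <- if (boundsOK) meanStepsFan(nTaxa) else NA_real_
  q <- if (nTaxa >= 2) {
    qq <- floor(log2(nTaxa)); if (2^(qq + 1) <= nTaxa) qq <- qq + 1
    as.integer(qq)
  } else NA_integer_
  x <- if (!is.na(q)) as.integer(nTaxa - 2^q) else NA_integer_

  new("KeyMetrics", keyId = key@keyId, nTaxa = as.integer(nTaxa),
      nCouplets = as.integer(nCouplets),
      nCoupletsExpected = as.integer(nTaxa - 1L),
      sActual = sActual, sMax = sMax, sMin = sMin, q = q, x = x,
      isMaxFan = if (is.na(sActual) || is.na(sMin)) NA
                 else abs(sActual - sMin) < 1e-9,
      depthRange = as.integer(range(allDepths)))
}

#' Couplet-count discrepancy
#'
#' A strictly dichotomous key in which every taxon keys out exactly once has
#' n - 1 couplets for n taxa. Returns the signed departure from that
#' expectation: duplicated taxa push the count up, polychotomies push it
#' down.
#'
#' @param key A \linkS4class{Key}.
#' @return Integer: observed couplets minus (n_taxa - 1).
#' @export
coupletCountDiscrepancy <- function(key) {
  g <- buildKeyGraph(key)
  length(key@couplets) - (length(g@taxonPaths) - 1L)
}

#' Prune a key to a set of terminal taxa
#'
#' Surveys of generic-level keys include only couplets that eventually lead
#' to a generic-level identification; this filter keeps the named terminals,
#' drops leads ending in any other taxon, and removes couplets left with
#' fewer than two leads by splicing the surviving lead's target into the
#' parent.
#'
#' @param key A \linkS4class{Key}.
#' @param keep Character vector of terminal taxon names to keep (matched
#'   after \code{\link{normalizeTaxon}}).
#' @return A pruned \linkS4class{Key}.
#' @export
pruneKeyToTaxa <- function(key, keep) {
  keepN <- normalizeTaxon(keep)
  cps <- key@couplets
  nums <- vapply(cps, coupletNumber, integer(1))
  repeat {
    changed <- FALSE
    # drop leads whose taxon is not kept
    for (i in seq_along(cps)) {
      cp <- cps[[i]]
      ok <- vapply(cp@leads, function(ld)
        is.na(ld@targetTaxon) || normalizeTaxon(ld@targetTaxon) %in% keepN,
        logical(1))
      if (!all(ok)) {
        changed <- TRUE
        kept <- cp@leads[ok]
        if (length(kept) >= 2L) {
          cps[[i]] <- Couplet(cp@number, kept, cp@retraceRef)
        } else if (length(kept) == 1L) {
          # splice: redirect every reference to this couplet to the
          # surviving lead's target
          surv <- kept[[1]]
          for (j in seq_along(cps)) {
            cpj <- cps[[j]]
            lds <- lapply(cpj@leads, function(ld) {
              if (!is.na(ld@targetCouplet) &&
                  ld@targetCouplet == cp@number) {
                if (!is.na(surv@targetCouplet)) {
                  ld@targetCouplet <- surv@targetCouplet
                } else {
                  ld@targetCouplet <- NA_integer_
                  ld@targetTaxon <- surv@targetTaxon
                }
              }
              ld
            })
            cps[[j]] <- Couplet(cpj@number, lds, cpj@retraceRef)
          }
          cps[[i]] <- NULL
        } else {
          cps[[i]] <- NULL
        }
        break
      }
    }
    if (!changed) break
  }
  if (!length(cps)) stop("pruning removed every couplet")
  Key(cps, keyId = key@keyId, title = key@title, scope = key@scope)
}
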