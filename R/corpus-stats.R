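#' @include rubric.R
NULL

#' Key prevalence by group
#'
#' Tabulates, per group (insect order, journal, ...), how many papers there
#' are, how many include a key, the proportion, and the corresponding counts
#' of newly described genera. Groups with no more than \code{poolThreshold}
#' papers are pooled into an "other" group, mirroring the practice of
#' analyzing only the well-represented groups individually.
#'
#' @param corpus data.frame of paper metadata (rows as from
#'   \code{\link{paperMetadata}}).
#' @param groupField Column to group by, e.g. "order" or "journal".
#' @param poolThreshold Integer; groups with <= this many papers are pooled.
#' @return data.frame: group, nPapers, nWithKey, prop, nNewGenera,
#'   nNewGeneraKeyed.
#' @export
proportionsByGroup <- function(corpus, groupField, poolThreshold = 20L) {
  stopifnot(groupField %in% names(corpus))
  g <- as.character(corpus[[groupField]])
  counts <- table(g)
  pooled <- names(counts)[counts <= poolThreshold]
  g[g %in% pooled] <- "other"
  out <- do.call(rbind, lapply(split(seq_len(nrow(corpus)), g), function(idx) {
    sub <- corpus[idx, , drop = FALSE]
    data.frame(group = g[idx[1]],
               nPapers = nrow(sub),
               nWithKey = sum(sub$hasKey),
               prop = mean(sub$hasKey),
               nNewGenera = sum(sub$nNewGenera),
               nNewGeneraKeyed = sum(sub$nNewGenera[sub$hasKey]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$group), , drop = FALSE]
}

#' Pearson chi-square test on a contingency table
#'
#' The plain Pearson statistic \eqn{\sum (O-E)^2/E} with
#' \eqn{df = (r-1)(c-1)} and an upper-tail chi-square p value; no continuity
#' correction by default (Yates available via \code{correct = TRUE}).
#'
#' @param table Matrix of counts (r x c), all expected counts positive.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return List: statistic, df, p.
#' @export
pearsonChiSquare <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("all expected counts must be positive")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Pooled two-proportion z test
#'
#' \eqn{z = (p_1 - p_2) / \sqrt{\bar p (1-\bar p)(1/n_1 + 1/n_2)}} with the
#' pooled proportion \eqn{\bar p = (x_1+x_2)/(n_1+n_2)}; the two-sided p
#' comes from the normal tail. Swapping the groups negates z and leaves p
#' unchanged.
#'
#' @param x1,n1,x2,n2 Successes and trials in the two groups.
#' @return List: z, p (two-sided).
#' @export
twoProportionZ <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

# U statistic of sample a given the combined midranks
uFromRanks <- function(ranksA, nA, nB) sum(ranksA) - nA * (nA + 1) / 2

#' Mann-Whitney U test
#'
#' Computes \eqn{U = \min(U_a, U_b)} using midranks for ties. For combined
#' sample sizes of at most \code{exactLimit} the two-sided p value is exact,
#' by complete enumeration of all assignments of the observed ranks to the
#' two groups (counting assignments whose U deviates from the null mean
#' \eqn{n_a n_b / 2} at least as much as observed). For larger samples the
#' normal approximation with the tie correction
#' \eqn{\sigma^2 = \frac{n_a n_b}{12}\left((N+1) -
#'   \frac{\sum (t^3 - t)}{N(N-1)}\right)} is used.
#'
#' @param a,b Numeric samples.
#' @param exactLimit Maximum combined size for exact enumeration.
#' @return List: U, p (two-sided), method ("exact" or "normal").
#' @export
mannWhitneyU <- function(a, b, exactLimit = 12L) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  nA <- length(a)
  nB <- length(b)
  N <- nA + nB
  r <- rank(c(a, b))
  uA <- uFromRanks(r[seq_len(nA)], nA, nB)
  uB <- nA * nB - uA
  U <- min(uA, uB)
  mu <- nA * nB / 2

  if (N <= exactLimit) {
    dev <- abs(uA - mu)
    hits <- 0L
    total <- 0L
    for (idx in utils::combn(N, nA, simplify = FALSE)) {
      u <- uFromRanks(r[idx], nA, nB)
      total <- total + 1L
      if (abs(u - mu) >= dev - 1e-12) hits <- hits + 1L
    }
    return(list(U = U, p = hits / total, method = "exact"))
  }

  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nA * nB / 12 * ((N + 1) - tieCorr)
  z <- if (sigma2 == 0) 0 else (uA - mu) / sqrt(sigma2)
  list(U = U, p = 2 * stats::pnorm(-abs(z)), method = "normal")
}
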