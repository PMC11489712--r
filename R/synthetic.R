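#' @include corpus-stats.R
NULL

# run code with a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Bank of contrasted morphological phrase pairs: element [1] goes in the
# first lead, [2] in the second; both open with the same subject word so the
# shallow contrast pairing has realistic positives.
featureBank <- function() {
  list(
    c("head longer than wide", "head shorter than wide"),
    c("hind tibia with apicoventral spines",
      "hind tibia lacking apicoventral spines, surface flat"),
    c("pronotum densely punctate", "pronotum smooth"),
    c("forewing with two submarginal cells",
      "forewing with three submarginal cells"),
    c("antenna with 12 segments", "antenna with 13 segments"),
    c("clypeus convex in profile", "clypeus flat in profile"),
    c("mesoscutum dull", "mesoscutum shining"),
    c("eyes bare", "eyes hairy"),
    c("scutellum rounded posteriorly", "scutellum angulate posteriorly"),
    c("tarsal claws simple", "tarsal claws toothed"),
    c("abdomen petiolate", "abdomen sessile"),
    c("wing membrane infuscate", "wing membrane hyaline"),
    c("mandible bidentate", "mandible tridentate"),
    c("ocelli present", "ocelli absent"),
    c("labial palpus with four segments", "labial palpus with three segments"),
    c("propodeum carinate", "propodeum smooth dorsally"),
    c("vertex elevated above eyes", "vertex level with eyes"),
    c("maxillary palpus elongate, reaching base of mandible",
      "maxillary palpus short, not reaching base of mandible"),
    c("metasoma red", "metasoma black"),
    c("frons coarsely sculptured", "frons finely sculptured"))
}

# phrases whose subject word appears nowhere in the bank above; used for
# uncontrasted-feature injection
unpairedBank <- function() {
  c("gena swollen behind eye", "sternum keeled medially",
    "tegula enlarged", "galea striate", "occiput carinate")
}

capitalize1 <- function(x) {
  sub("^(.)", "\\U\\1", x, perl = TRUE)
}

#' Generator configuration
#'
#' @param nTaxa Number of terminal taxa (>= 2).
#' @param balance Real in [0, 1]: 0 builds the maximally unbalanced
#'   caterpillar (comb), 1 the maximally balanced tree (fan); intermediate
#'   values interpolate through biased split proportions.
#' @param seed Integer seed; a fixed seed reproduces the key byte for byte.
#' @param defectRates Named list mapping defect category ("leap-frog",
#'   "numbering-error", "polychotomy", "looped", "monothetic",
#'   "qualifier-word", "uncontrasted", "duplicate-taxon") to either an exact
#'   injection count (an integer such as \code{1L}, or any value above one)
#'   or a per-eligible-couplet probability (a double in [0, 1]; 1.0 hits
#'   every eligible couplet).
#' @param illustrationRate Probability that a lead cites a figure.
#' @param retracing Emit "N(M)" retrace references on non-root couplets.
#' @param featureCountRange Integer (min, max) features per lead.
#' @return Named list of settings for \code{\link{generateKey}}.
#' @export
keyGenConfig <- function(nTaxa, balance = 0.5, seed = 1L,
                         defectRates = list(), illustrationRate = 0,
                         retracing = TRUE, featureCountRange = c(2L, 3L)) {
  stopifnot(nTaxa >= 2, balance >= 0, balance <= 1,
            illustrationRate >= 0, illustrationRate <= 1,
            length(featureCountRange) == 2,
            featureCountRange[1] >= 1,
            featureCountRange[2] >= featureCountRange[1])
  known <- c("leap-frog", "numbering-error", "polychotomy", "looped",
             "monothetic", "qualifier-word", "uncontrasted",
             "duplicate-taxon")
  if (length(defectRates) &&
      !all(names(defectRates) %in% known))
    stop("unknown defect category in defectRates: ",
         paste(setdiff(names(defectRates), known), collapse = ", "))
  list(nTaxa = as.integer(nTaxa), balance = balance,
       seed = as.integer(seed), defectRates = defectRates,
       illustrationRate = illustrationRate, retracing = retracing,
       featureCountRange = as.integer(featureCountRange))
}

#' Generate a clean random key topology
#'
#' Builds a strictly dichotomous key spanning the comb-fan continuum. At
#' each internal split of the remaining m taxa the first lead takes s of
#' them, with s = 1 at balance 0 (yielding the caterpillar, whose mean path
#' equals the comb closed form) and s = floor(m/2) at balance 1 (the
#' balanced tree, whose mean path equals the fan closed form); intermediate
#' balance draws s from a binomial biased accordingly. Couplets are numbered
#' in pre-order, so the first lead that continues always continues to the
#' next couplet (no leap-frogging by construction). Taxa are named
#' "Genus_001", "Genus_002", ... Features come from a template bank of
#' contrasted phrase pairs, treated in parallel in the two leads.
#'
#' @param nTaxa,balance,seed,illustrationRate,retracing,featureCountRange
#'   See \code{\link{keyGenConfig}}.
#' @param keyId,title Key identification.
#' @return A clean \linkS4class{Key} (no lint defects in any syntactic
#'   category by construction).
#' @export
generateTopology <- function(nTaxa, balance, seed,
                             retracing = TRUE,
                             featureCountRange = c(2L, 3L),
                             illustrationRate = 0,
                             keyId = sprintf("sim-%d-%s", nTaxa, seed),
                             title = "") {
  if (nTaxa < 2) stop("nTaxa must be >= 2")
  withSeed(seed, {
    bank <- featureBank()
    env <- new.env()
    env$counter <- 1L
    env$taxon <- 0L
    env$fig <- 0L
    env$rows <- list()

    newTaxon <- function() {
      env$taxon <- env$taxon + 1L
      sprintf("Genus_%03d", env$taxon)
    }
    genNode <- function(m, parent) {
      myNum <- env$counter
      env$counter <- env$counter + 1L
      half <- m %/% 2L
      s <- if (balance <= 0) 1L
           else if (balance >= 1) half
           else 1L + stats::rbinom(1, half - 1L, balance)
      k <- sample(seq(featureCountRange[1], featureCountRange[2]), 1)
      idx <- sample(seq_along(bank), k)
      mk <- function(cnt) {
        if (cnt == 1L) list(kind = "taxon", value = newTaxon())
        else list(kind = "couplet", value = genNode(cnt, myNum))
      }
      left <- mk(s)
      right <- mk(m - s)
      env$rows[[myNum]] <- list(num = myNum, parent = parent,
                                templates = idx, left = left, right = right)
      myNum
    }
    genNode(as.integer(nTaxa), NA_integer_)

    cps <- lapply(env$rows, function(row) {
      mkLead <- function(side, ordinal) {
        phr <- vapply(bank[row$templates], `[`, character(1),
                      i = if (ordinal == 1L) 1L else 2L)
        phr[1] <- capitalize1(phr[1])
        if (illustrationRate > 0 && stats::runif(1) < illustrationRate) {
          env$fig <- env$fig + 1L
          phr[1] <- paste0(phr[1], sprintf(" (Fig. %d)", env$fig))
        }
        tgt <- if (side$kind == "taxon") side$value else side$value
        ld <- Lead(phr, target = tgt, ordinal = ordinal,
                   figureRefs = extractFigureRefs(paste(phr, collapse = "; ")))
        ld
      }
      Couplet(row$num,
              list(mkLead(row$left, 1L), mkLead(row$right, 2L)),
              retraceRef = if (retracing) row$parent else NA_integer_)
    })
    Key(cps, keyId = keyId, title = title, style = "dichotomous")
  })
}

#' Generate a key from a configuration, with labeled defect injection
#'
#' \code{generateKey} builds the clean topology for a configuration and then
#' applies \code{\link{injectDefects}}.
#'
#' @param config From \code{\link{keyGenConfig}}.
#' @return \code{generateKey}: list with \code{key} and \code{groundTruth};
#'   see \code{\link{injectDefects}}.
#' @export
generateKey <- function(config) {
  key <- generateTopology(config$nTaxa, config$balance, config$seed,
                          retracing = config$retracing,
                          featureCountRange = config$featureCountRange,
                          illustrationRate = config$illustrationRate)
  injectDefects(key, config)
}

# A rate given as an R integer (1L, 2L, ...) or any value above one is an
# exact injection count; a double in [0, 1] is a per-eligible-couplet
# probability (so 1.0 hits every eligible couplet, while 1L hits one).
nInjections <- function(rate, nEligible, seed) {
  if (is.null(rate) || nEligible < 1L) return(0L)
  if (is.integer(rate) || rate > 1) min(as.integer(rate), nEligible)
  else stats::rbinom(1, nEligible, rate)
}

#' Inject labeled defects into a clean key
#'
#' Each injection transforms the key in the way its lint detector defines
#' the defect, and records the locus: leap-frog swaps the lead order of an
#' eligible couplet (both leads continuing) so the first lead jumps; a
#' numbering error renumbers a terminal couplet to duplicate another number;
#' a polychotomy adds a third lead keying out an extra taxon; a loop
#' retargets a taxon lead onto a couplet that already has a parent;
#' monothetic injection truncates both leads to a single feature; a
#' qualifier word is inserted into a feature; an uncontrasted feature (whose
#' subject appears nowhere in the sibling lead) is appended; duplicate-taxon
#' renames one terminal to another existing name.
#'
#' @param key A clean \linkS4class{Key} from \code{\link{generateTopology}}.
#' @param config From \code{\link{keyGenConfig}}; \code{defectRates} drives
#'   what is injected, \code{seed} (offset) drives where.
#' @return List: \code{key} (the defective key), \code{groundTruth} (list
#'   with \code{injected}, a data.frame of category/couplet/lead loci, and
#'   \code{trueMetrics}, the \linkS4class{KeyMetrics} of the clean
#'   topology).
#' @export
injectDefects <- function(key, config) {
  trueMetrics <- computeMetrics(key)
  rates <- config$defectRates
  gt <- data.frame(category = character(), couplet = integer(),
                   lead = integer(), stringsAsFactors = FALSE)
  if (!length(rates))
    return(list(key = key, groundTruth = list(injected = gt,
                                              trueMetrics = trueMetrics)))

  withSeed(config$seed + 1000003L, {
    cps <- key@couplets
    nums <- vapply(cps, coupletNumber, integer(1))
    structUsed <- integer()
    addGT <- function(category, couplet = NA_integer_, lead = NA_integer_) {
      gt <<- rbind(gt, data.frame(category = category,
        couplet = as.integer(couplet), lead = as.integer(lead),
        stringsAsFactors = FALSE))
    }
    pick <- function(eligible, n) {
      eligible <- setdiff(eligible, structUsed)
      if (length(eligible) < 1L || n < 1L) return(integer())
      sel <- if (length(eligible) == 1L) eligible
             else sample(eligible, min(n, length(eligible)))
      structUsed <<- c(structUsed, sel)
      sel
    }
    leadTargets <- function(cp) vapply(cp@leads, function(ld)
      ld@targetCouplet, integer(1))

    # --- monothetic: truncate features -------------------------------------
    nMono <- nInjections(rates[["monothetic"]], length(cps), config$seed)
    monoSel <- pick(seq_along(cps), nMono)
    for (i in monoSel) {
      cp <- cps[[i]]
      lds <- lapply(cp@leads, function(ld) {
        ld@features <- ld@features[1]
        ld@figureRefs <- extractFigureRefs(ld@features)
        ld
      })
      cps[[i]] <- Couplet(cp@number, lds, cp@retraceRef)
      addGT("monothetic", cp@number)
    }
    structUsed <- integer()

    # --- qualifier word ----------------------------------------------------
    lex <- ambiguityLexicon()
    nQual <- nInjections(rates[["qualifier-word"]], length(cps), config$seed)
    qualSel <- pick(seq_along(cps), nQual)
    for (i in qualSel) {
      cp <- cps[[i]]
      li <- sample(1:2, 1)
      ld <- cp@leads[[li]]
      fi <- sample(seq_along(ld@features), 1)
      w <- sample(lex$qualifierWords, 1)
      ld@features[fi] <- sub("^(\\S+)", paste0("\\1 ", w), ld@features[fi])
      lds <- cp@leads
      lds[[li]] <- ld
      cps[[i]] <- Couplet(cp@number, lds, cp@retraceRef)
      addGT("qualifier-word", cp@number, li)
    }
    structUsed <- integer()

    # --- uncontrasted feature (never on a monothetic-injected couplet,
    #     which the appended feature would de-monotheticize) ----------------
    nUnc <- nInjections(rates[["uncontrasted"]],
                        length(cps) - length(monoSel), config$seed)
    extra <- unpairedBank()
    structUsed <- monoSel
    uncSel <- pick(seq_along(cps), nUnc)
    for (i in uncSel) {
      cp <- cps[[i]]
      li <- sample(1:2, 1)
      ld <- cp@leads[[li]]
      ld@features <- c(ld@features, sample(extra, 1))
      lds <- cp@leads
      lds[[li]] <- ld
      cps[[i]] <- Couplet(cp@number, lds, cp@retraceRef)
      addGT("uncontrasted", cp@number, li)
    }
    # structural injections must not land on wording loci: a third lead
    # would exempt the couplet from the two-lead wording detectors
    structUsed <- unique(c(monoSel, qualSel, uncSel))

    # --- leap-frog: swap lead order where both leads continue ---------------
    eligible <- which(vapply(cps, function(cp)
      all(!is.na(leadTargets(cp))), logical(1)))
    nLeap <- nInjections(rates[["leap-frog"]], length(eligible), config$seed)
    for (i in pick(eligible, nLeap)) {
      cp <- cps[[i]]
      cps[[i]] <- Couplet(cp@number, cp@leads[c(2, 1)], cp@retraceRef)
      # wording injections recorded before the swap move with their lead
      sel <- !is.na(gt$couplet) & gt$couplet == cp@number & !is.na(gt$lead)
      gt$lead[sel] <- 3L - gt$lead[sel]
      addGT("leap-frog", cp@number)
    }

    # --- looped: retarget a taxon lead onto an already-parented couplet ----
    nLoop <- nInjections(rates[["looped"]], 1L, config$seed)
    if (nLoop > 0L && length(cps) >= 3L) {
      ancestorsOf <- function(num) {
        anc <- integer()
        cur <- num
        repeat {
          idx <- which(nums == cur)[1]
          p <- cps[[idx]]@retraceRef
          if (is.na(p)) {
            # fall back to edge search when retrace refs are absent
            p <- NA_integer_
            for (j in seq_along(cps)) for (ld in cps[[j]]@leads)
              if (!is.na(ld@targetCouplet) && ld@targetCouplet == cur)
                p <- cps[[j]]@number
            if (is.na(p)) break
          }
          anc <- c(anc, p)
          cur <- p
          if (length(anc) > length(cps)) break
        }
        anc
      }
      # restrict hosts to terminal couplets (both leads taxa) so the
      # retargeted lead can never create a spurious leap-frog pattern
      hosts <- which(vapply(cps, function(cp)
        all(is.na(leadTargets(cp))), logical(1)))
      hosts <- setdiff(hosts, structUsed)
      for (hi in hosts[sample.int(length(hosts))]) {
        host <- cps[[hi]]
        anc <- c(ancestorsOf(host@number), host@number)
        # target must already have a parent (any non-root couplet)
        candidates <- setdiff(nums[-1], anc)
        if (!length(candidates)) next
        d <- if (length(candidates) == 1L) candidates
             else sample(candidates, 1)
        lds <- host@leads
        lds[[2]]@targetTaxon <- NA_character_
        lds[[2]]@targetCouplet <- as.integer(d)
        cps[[hi]] <- Couplet(host@number, lds, host@retraceRef)
        # neither the host nor the loop target may be touched by later
        # structural injections (renumbering the target would undo the loop)
        structUsed <- c(structUsed, hi, which(nums == d))
        addGT("looped", d)
        break
      }
    }

    # --- polychotomy: add a third lead keying out an extra taxon ------------
    nPoly <- nInjections(rates[["polychotomy"]], length(cps), config$seed)
    for (i in pick(seq_along(cps), nPoly)) {
      cp <- cps[[i]]
      extraTaxon <- sprintf("Genus_x%03d", i)
      phr <- capitalize1(featureBank()[[sample(20, 1)]][1])
      # keep the illustration coverage class unchanged in fully (un)illustrated
      # keys so the polychotomy is the only consequence of this injection
      if (config$illustrationRate > 0) {
        env2 <- sprintf(" (Fig. 9%02d)", i %% 100)
        phr <- paste0(phr, env2)
      }
      lds <- c(cp@leads, Lead(phr, target = extraTaxon,
                              ordinal = length(cp@leads) + 1L,
                              figureRefs = extractFigureRefs(phr)))
      cps[[i]] <- Couplet(cp@number, lds, cp@retraceRef)
      addGT("polychotomy", cp@number)
    }

    # --- numbering error: renumber a terminal couplet to a duplicate --------
    nNum <- nInjections(rates[["numbering-error"]], 1L, config$seed)
    if (nNum > 0L && length(cps) >= 3L) {
      terminals <- which(vapply(cps, function(cp)
        all(is.na(leadTargets(cp))), logical(1)))
      terminals <- setdiff(terminals, c(structUsed, 1L))
      if (length(terminals)) {
        i <- if (length(terminals) == 1L) terminals
             else sample(terminals, 1)
        oldNum <- cps[[i]]@number
        others <- setdiff(nums, oldNum)
        d <- if (length(others) == 1L) others else sample(others, 1)
        cps[[i]] <- Couplet(d, cps[[i]]@leads, cps[[i]]@retraceRef)
        gt$couplet[gt$couplet == oldNum & !is.na(gt$couplet)] <- as.integer(d)
        addGT("numbering-error", d)
      }
    }

    # --- duplicate taxon -----------------------------------------------------
    nDup <- nInjections(rates[["duplicate-taxon"]], 1L, config$seed)
    if (nDup > 0L) {
      taxLoci <- list()
      for (i in seq_along(cps)) for (li in seq_along(cps[[i]]@leads))
        if (!is.na(cps[[i]]@leads[[li]]@targetTaxon))
          taxLoci[[length(taxLoci) + 1L]] <- c(i, li)
      if (length(taxLoci) >= 2L) {
        sel <- sample(length(taxLoci), 2)
        src <- taxLoci[[sel[1]]]
        dst <- taxLoci[[sel[2]]]
        nm <- cps[[src[1]]]@leads[[src[2]]]@targetTaxon
        lds <- cps[[dst[1]]]@leads
        lds[[dst[2]]]@targetTaxon <- nm
        cps[[dst[1]]] <- Couplet(cps[[dst[1]]]@number, lds,
                                 cps[[dst[1]]]@retraceRef)
        addGT("duplicate-taxon")
      }
    }

    key2 <- Key(cps, keyId = key@keyId, title = key@title,
                scope = key@scope)
    list(key = key2, groundTruth = list(injected = gt,
                                        trueMetrics = trueMetrics))
  })
}

#' Generate a synthetic corpus of paper metadata
#'
#' Emulates the per-paper metadata table of a survey of new-genus
#' descriptions: each paper belongs to a group (insect order by default),
#' includes a key with the group's configured probability, and has its
#' remaining fields drawn from configurable marginal rates chosen to mimic
#' the variation such surveys observe (availability around three quarters,
#' discoverability of the word "key" around 70 percent, a long-tailed genus
#' count per key, and so on).
#'
#' @param nPapers Total number of papers.
#' @param groupSpecs data.frame with columns \code{group} and \code{prob}
#'   (per-group probability that a paper includes a key) and optionally
#'   \code{weight} (relative share of papers; equal by default).
#' @param seed Integer seed.
#' @param marginals Named list overriding marginal rates:
#'   \code{freelyAvailable}, \code{availableViaLibrary},
#'   \code{keyDiscoverable}, \code{scopeStatement}, \code{habitus},
#'   \code{illustrationAllLeads}, \code{diagnosisAll}.
#' @param journals Character vector of journal names sampled uniformly.
#' @return data.frame with one row per paper, columns as
#'   \code{\link{paperMetadata}}.
#' @export
generateCorpus <- function(nPapers, groupSpecs, seed,
                           marginals = list(),
                           journals = c("ZT", "ZK", "EJT", "SE", "ZJLS")) {
  stopifnot(nPapers >= 1, all(c("group", "prob") %in% names(groupSpecs)))
  m <- list(freelyAvailable = 0.74, availableViaLibrary = 0.05,
            keyDiscoverable = 0.71, scopeStatement = 0.58,
            habitus = 0.94, diagnosisAll = 0.25)
  m[names(marginals)] <- marginals
  withSeed(seed, {
    w <- if ("weight" %in% names(groupSpecs)) groupSpecs$weight
         else rep(1, nrow(groupSpecs))
    grp <- sample(seq_len(nrow(groupSpecs)), nPapers, replace = TRUE,
                  prob = w / sum(w))
    hasKey <- stats::rbinom(nPapers, 1, groupSpecs$prob[grp]) == 1
    free <- stats::rbinom(nPapers, 1, m$freelyAvailable) == 1
    lib <- !free & stats::rbinom(nPapers, 1, m$availableViaLibrary) == 1
    disc <- stats::rbinom(nPapers, 1, m$keyDiscoverable) == 1
    loc <- ifelse(disc, sample(c("abstract", "title", "keywords"), nPapers,
                               replace = TRUE, prob = c(0.8, 0.12, 0.08)),
                  "")
    nNew <- 1L + stats::rpois(nPapers, 0.35)
    nInKey <- ifelse(hasKey,
                     pmax(nNew, 2L + stats::rnbinom(nPapers, mu = 9,
                                                    size = 1.2)),
                     0L)
    data.frame(
      paperId = sprintf("paper_%04d", seq_len(nPapers)),
      keyId = ifelse(hasKey, sprintf("key_%04d", seq_len(nPapers)), ""),
      order = as.character(groupSpecs$group[grp]),
      journal = sample(journals, nPapers, replace = TRUE),
      freelyAvailable = free,
      availableViaLibrary = lib,
      keyTermLocation = loc,
      scopeStatementPresent = stats::rbinom(nPapers, 1,
                                            m$scopeStatement) == 1,
      scopeStatementLocation = sample(
        c("above-key", "introduction", "results-elsewhere", "below-key",
          "methods", "diagnosis"), nPapers, replace = TRUE,
        prob = c(0.38, 0.38, 0.2, 0.013, 0.013, 0.014)),
      sexRestrictionStated = NA,
      casteRestrictionStated = NA,
      diagnosisCoverage = sample(c("all", "some-others", "new-genera-only",
                                   "none"), nPapers, replace = TRUE,
        prob = c(m$diagnosisAll, 0.13, 1 - m$diagnosisAll - 0.13 - 0.06,
                 0.06)),
      habitusPresent = stats::rbinom(nPapers, 1, m$habitus) == 1,
      habitusKind = sample(c("photograph", "drawing", "SEM"), nPapers,
                           replace = TRUE, prob = c(0.9, 0.07, 0.03)),
      imagePlacement = sample(c("adjacent", "adjacent-page", "hyperlinked",
                                "grouped-at-key", "dispersed", "none"),
                              nPapers, replace = TRUE,
                              prob = c(0.05, 0.06, 0.015, 0.02, 0.42,
                                       0.435)),
      nNewGenera = nNew,
      nGeneraInKey = nInKey,
      keyInSupplementOnly = stats::rbinom(nPapers, 1, 0.015) == 1,
      emendationStandalone = NA,
      hasKey = hasKey,
      stringsAsFactors = FALSE)
  })
}
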