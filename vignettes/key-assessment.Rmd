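---
title: "Assessing dichotomous identification keys with keylint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing dichotomous identification keys with keylint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keylint)
```

## The object of study

A dichotomous identification key presents a user with numbered *couplets*,
each offering two *leads*; a lead lists one or more discriminating *features*
and ends either in a taxon name or in the number of the couplet to continue
with. `keylint` models a key as a rooted decision tree over its terminal
taxa, represented by S4 classes (`Lead`, `Couplet`, `Key`) with a derived
`KeyGraph` resolving parent/child edges, the root, and every taxon's path
lengths.

A deliberate design choice is that **malformed keys are representable**.
Published keys contain duplicated couplet numbers, targets pointing at absent
couplets, couplets reachable by two paths ("looped" keys), trichotomies, and
taxa keying out several times. The constructors accept all of this; every
pathology is reported as a row in a defect table (a data frame with a closed
category vocabulary, `defectCategories()`) rather than as an exception,
because an assessment tool that refuses malformed keys cannot assess the
keys most in need of assessment. Taxon identity is exact string match after
whitespace squeezing and case folding; a duplicated terminal is one taxon
with several paths.

## Path-length metrics

Path length counts couplets traversed *including* the deciding couplet, so a
taxon keyed out at the root has path length 1; a 16-taxon caterpillar
therefore spans depths 1 through 15. The mean over taxa (`sActual`, with a
duplicated taxon's occurrences averaged per taxon first) is compared with
two closed forms: the comb (caterpillar) maximum `meanStepsComb(n) =
(n+1)/2 − 1/n` and the fan minimum `meanStepsFan(n) = (Q(2^Q − x) +
(Q+1)·2x)/n`, `Q = ⌊log2 n⌋`, `x = n − 2^Q`. The fan form equals `log2 n`
exactly when `x = 0`. The test suite verifies both forms for `n = 2..64`
against independent oracles: a dynamic program minimizing external path
length over all binary trees, and the caterpillar depth sum.

Keys with any polychotomy, loop, or unreachable couplet keep `sActual`
(loops excepted) but get `NA` bounds, since the closed forms presuppose
strict dichotomy. For a taxon reachable only through a looped couplet no
single path length is defined, so looped keys get `NA` for `sActual` as
well and the loop is flagged; both paths remain visible in the `KeyGraph`.

## Parsing and rendering

`parseKey()` accepts the dominant printed dialect: headers `N`, `N.`, or
`N(M)` (the `M` being the retrace reference to the couplet that led here),
continuation leads opening with a dash or with the couplet number repeated
with a prime mark, trailing integers as couplet targets and trailing
capitalized names (optionally with author strings) as taxa. Yoked keys with
letter-pair markers (`A.` ... `AA.`) map onto the same couplet model with
style `"yoked"`. Features split on semicolons only: in the example lead
"hind tibia lacking apicoventral spines, surface flat" the comma marks a
subordinate clause of one feature, and splitting on commas would inflate
feature counts. Bracketed or parenthesized text immediately before the
target that does not match the figure-citation pattern is captured as
*ancillary* information and excluded from wording analyses, since it is by
design not decisive. Figure citations are extracted per lead but left
inside the feature text, which keeps `renderKey()` an exact inverse:
`parseKey(renderKey(k))` is structurally equal to `k` for every defect-free
key, a property exercised over hundreds of generated keys. The parser
conserves lines — every input line is either consumed or listed in
`unparsedLines` — and raises only when no couplet header is found at all.

## Lint detectors

Each detector is a pure function from key (or couplet) to defect rows, so
lint output is deterministic.

* **Leap-frog** (`detectLeapfrog`): the first lead targets a couplet other
  than `N + 1` while the second targets exactly `N + 1` — the reverse of
  standard practice. Defined only where both leads continue.
* **Retracing** (`detectRetracing`): by default a key supports retracing if
  every non-root couplet that does not continue directly from the couplet
  above it carries an `N(M)` reference (a strict mode requires references
  everywhere); references naming a couplet whose leads do not target the
  current one are numbering errors. Keys of two or fewer couplets return
  `NA` — the question does not arise.
* **Numbering** (`detectNumberingErrors`): duplicate numbers, gaps in the
  `1..max` sequence, and leads targeting their own ancestor (cycles).
* **Monothetic couplets** (`detectMonothetic`): a couplet whose every lead
  rests on a single feature fails entirely when that structure is missing;
  the per-couplet table, overall proportion, and whether every taxon's path
  crosses at least one such couplet are returned.
* **Parallelism and contrast** (`detectParallelContrast`): features are
  paired across leads by their first content word (a stoplist drops
  articles, prepositions, and hedging adverbs). Deeper linguistic analysis
  is deliberately out of scope — the pairing is shallow by design, mirroring
  assessment by eye, and the stoplist is configurable. Unpaired features are
  uncontrasted; paired features in a different order are non-parallel; leads
  sharing no pair at all block comparison entirely.
* **Wording ambiguity** (`detectAmbiguity`): hedging qualifiers ("usually",
  "often", ...), relative markers and bare comparatives without an
  accompanying measurement, ratio, or "...er than" standard, and numeric
  ranges for the same measurement that overlap between the two leads. A
  relative or overlapping-range flag is dropped when both leads cite
  figures, because an illustration of both alternatives settles the
  comparison; a hedging qualifier is never dropped — no figure makes an
  "unusual" phenotype keyable. A couplet in which every feature of at least
  one lead remains flagged is entirely indecisive. On the ranges: the
  conventional prose formulation of this defect refers to "non-overlapping"
  ranges, but the canonical example pair (9–12 mm versus 11–15 mm) overlaps,
  and overlap is precisely what makes a couplet indecisive for a specimen at
  11.5 mm; the detector flags **overlap**.
* **Illustration coverage** (`detectIllustrationCoverage`): proportion of
  leads citing at least one figure, classified `none` / `partial` /
  `all-leads`.
* **Style** (`detectStyle`): yoked style, polychotomies, loops, duplicate
  taxa (informational), and leads keying out more than one taxon.

## The 17-criterion rubric

`scoreKey()` marks each criterion optimal, suboptimal, or not-applicable and
records the deciding defect category or metadata field (the audit trail).
The criteria cover availability, discoverability of the word "key", scope
statements, sex/caste restrictions, formatting, leap-frogs, dichotomy,
retracing, fan-shapedness, monothetic couplets, contrast, decisiveness,
illustration coverage and placement, diagnoses, habitus images, and
emendation independence. Not-applicable handling is explicit where the
source judgements were implicit:

* image placement is N/A when there are no images at all — the placement of
  nothing cannot be assessed; when some images exist, placement is scored;
* fan-shapedness is N/A for keys excluded from the bounds (polychotomies,
  loops) and auto-optimal for three or fewer taxa, where every dichotomous
  shape is already minimal;
* scope statements are auto-optimal for family-rank keys (where instructions
  may be deemed unnecessary), overridable via `familyRankAutoOptimal`;
* the sex/caste criterion scores the disjunction of failures and is N/A only
  when neither question arises.

All criteria are equally weighted — inventing weights would suggest a
precision the binary judgements do not have. `corpusRubricSummary()` uses
the sample (n − 1) standard deviation.

## Statistics

`pearsonChiSquare()` is the plain Pearson statistic (via `chisq.test`,
no continuity correction by default, Yates on request), `twoProportionZ()`
the pooled two-proportion z with two-sided normal p, and `mannWhitneyU()`
returns `U = min(Ua, Ub)` with midranks, an exact two-sided p by complete
enumeration of rank assignments for combined samples of at most 12 (the
enumeration definition — the probability of a U at least as far from
`na·nb/2` as observed — handles ties, which the standard exact algorithm
does not), and the tie-corrected normal approximation otherwise.

## The synthetic-data generator

`generateTopology(n, balance, seed)` spans the comb-fan continuum: at each
split of `m` remaining taxa the first lead takes `s` taxa with `s = 1` at
balance 0 (caterpillar) and `s = ⌊m/2⌋` at balance 1 (balanced tree, which
attains the fan bound); intermediate balance draws
`s = 1 + Binomial(⌊m/2⌋ − 1, balance)`, a monotone interpolation whose
endpoints are the tested contract. Couplets are numbered pre-order, so clean
keys never leap-frog; features come from a built-in bank of contrasted
morphological phrase pairs treated in parallel, so the contrast detector
sees realistic positives and negatives; figure citations are attached to the
first feature of a lead at the configured `illustrationRate`.

`injectDefects()` applies each defect the way its detector defines it and
records the locus: lead-order swaps (leap-frog), renumbering a terminal
couplet to a duplicate (numbering error, with downstream dangling reference
and gap as side effects), a third lead (polychotomy), retargeting a
terminal-couplet lead onto an already-parented couplet (loop), feature
truncation (monothetic), qualifier insertion, and appending a feature whose
subject occurs nowhere in the sibling lead (uncontrasted). Injections are
scheduled so they cannot mask one another (a structural injection never
lands on a wording locus; the loop target is protected from renumbering).
Rates given as R integers are exact counts; doubles in [0, 1] are
per-eligible-couplet probabilities. A fixed seed reproduces key text and
ground truth byte for byte, and the generator restores the caller's RNG
state.

`generateCorpus()` emulates a survey's per-paper metadata table: each paper
belongs to a group with a configured key-prevalence probability, and the
remaining fields are drawn from marginal rates chosen to sit in the range
such surveys report (availability near three quarters, discoverability near
70%, a long-tailed genus count per key with mean near 11, habitus images
nearly ubiquitous). What the generator does **not** emulate: real taxonomic
prose (wording comes from a small template bank), correlations between
metadata fields, within-journal conventions, or the heavy upper tail of key
sizes beyond a negative-binomial genus count. Passing tests on generated
corpora therefore demonstrate that the pipeline's measurements are correct
under known ground truth, not that any particular published corpus would
yield particular values.

## Numerical choices and problem sizes

Bound comparisons use a 1e−9 tolerance (`isMaxFan` is `|sActual − sMin| <
1e−9`). The fan form's `⌊log2 n⌋` is guarded against floating-point error at
exact powers of two. Degenerate inputs: `n < 2` is rejected for the closed
forms (a key needs two taxa); empty keys and keys resolving to no taxon are
errors; single-result rubric summaries return SD 0 with a flag. The test
suite verifies the closed forms against enumeration for `n = 2..64`,
generator endpoints for `n ∈ {4, 6, 16, 33, 128}`, the fan-comb sandwich
over 500 random keys, injection recovery over 500 keys, parse-render
identity over 200 keys, and chi-square type-I calibration over 2000
simulated null corpora of 300 papers — sizes chosen to make the stochastic
checks stable while keeping a full run in the low minutes.

## Known limitations

The contrast and ambiguity detectors are lexical, not semantic: synonymous
subjects ("metasoma"/"abdomen") pair as uncontrasted, and domain jargon is
not validated against any glossary. The parser handles the numbered-couplet
and yoked dialects but not matrix or interactive key formats, PDFs, or OCR
artifacts. No key-rebalancing optimizer is provided: the fan bound is used
to flag unbalanced keys, not to restructure them. Species-level keys'
infraspecific structure and nomenclatural validity of taxon names are out
of scope.
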