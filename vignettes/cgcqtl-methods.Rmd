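---
title: "Keyword-based candidate gene scoring and QTL connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Keyword-based candidate gene scoring and QTL connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative trait locus (QTL) mapping in rat models of experimentally
induced arthritis yields broad genomic intervals — dozens of loci that
together cover roughly half of the rat genome. Prioritizing candidate
genes within (and outside) those intervals is therefore a text-mining
problem as much as a genetic one. `cgcqtl` implements a complete, tested
version of a three-stage analysis:

1. **Candidate Gene Capture (CGC) scoring.** Each gene carries a
   descriptive free-text record (emulating an OMIM entry). A preset array
   of weighted keywords is scanned against the record; a gene's CGC score
   is the sum of the weights of all *distinct* matched keywords. A
   keyword's weight — its *relevance index* — is defined from literature
   co-occurrence counts as
   `100 * n(keyword AND reference term) / n(keyword)`, with "arthritis"
   as the default reference term.
2. **Genome partition.** Scored genes (CGC ≥ 0.1) are classified as
   inside or outside the union of arthritis QTL intervals, stratified
   into CGC-score bins, and each bin's inside/outside split is tested
   against the genome-wide proportion with a 1-df chi-square.
3. **QTL connectivity.** Record hyperlinks between genes are turned into
   an undirected gene graph. For QTLs mapped in two different crosses,
   every cross-cross QTL pair is tested — with a Yates-corrected 2×2
   chi-square — for having more connecting gene pairs than its gene-count
   product predicts. Connecting pairs where at least one gene has CGC ≥ 50
   are reported separately as strong-candidate pairs.

A seeded synthetic-data generator produces gene catalogs, QTL tables,
keyword sets, record corpora and link tables with controllable enrichment
effects, so the whole pipeline runs and is testable without any external
downloads.

## Keyword matching

The original application's matching rules are not published, so matching
here is defined explicitly and exposed as a switch:

* `match = "token"` (default): records and keywords are lower-cased and
  split on non-alphanumeric runs; a keyword matches only as a whole token,
  multi-word keywords as contiguous token sequences. "arthritis" does
  **not** match the token "osteoarthritis".
* `match = "substring"`: plain case-insensitive substring search.

Each keyword counts **once** per record regardless of repeats: the score
measures breadth of relevance, and bounded sums are what make the score
strata meaningful. Scores are invariant to text case and keyword order;
these invariants, plus exact agreement with a naive sliding-window oracle,
are enforced by property tests.

## The per-bin test

Score bins are half-open `[lower, upper)` with default edges
`0.1, 10, 20, 30, 50, 100, 200, Inf` (a score of exactly 100 falls in
100–200). Each bin's `(inside, outside)` counts are tested against the
expected proportions implied by the totals row — a 1-df Pearson
goodness-of-fit with no continuity correction. This construction
reproduces the published per-bin p-values for the reference
stratification bundled with the package (0.70, 0.10, 0.98, 0.59, 0.40,
0.73, 0.92) to two decimals; a 2×2 bin-versus-rest variant is available
(`variant = "2x2"`) and gives nearly identical values.

**A calibration caveat that is inherent to this construction:** the
genome-wide proportion is estimated from totals that *include* the bin
being tested. The bin count and its reference are therefore positively
coupled and the statistic is stochastically smaller than a true 1-df
chi-square — mildly for small bins, substantially for a bin holding most
genes. Under the synthetic null at the default scale (2403 genes) the
fraction of bin p-values below 0.05 is about 0.03, not 0.05, and a
Kolmogorov–Smirnov test against uniformity over thousands of pooled
replicate p-values detects the deficit. This conservatism is a property
of the published analysis design itself, faithfully reproduced; it makes
the reported per-bin p-values err on the side of *not* declaring
enrichment. The acceptance suite measures this honestly rather than
papering over it.

## The QTL-pair test

Gene–QTL membership uses individual QTL intervals (not the flattened
union), so a gene inside two overlapping QTLs contributes to both; for
inside/outside classification the union is used so each gene counts once.
Overlap semantics are any-base overlap on 1-based inclusive coordinates
(`overlap = "any"`; `"full"` requires containment).

For QTL pair (q1 from cross 1, q2 from cross 2), with the observed
connection matrix `O` over all admissible pairs:

* `a = O[q1, q2]`, `b` = q1's other cross-cross connections, `c` = q2's
  other cross-cross connections, `d` = the rest;
* Yates statistic `N(|ad − bc| − N/2)² / ((a+b)(c+d)(a+c)(b+d))`, clamped
  to 0 when `|ad − bc| ≤ N/2`, p from the 1-df chi-square;
* the null expectation reported alongside is
  `expected = T · n1·n2 / Σ n_i·n_j` with `T` the total cross-cross edge
  count — expectations sum exactly to `T`.

The published pair p-values for the original link data are **not**
recomputable (the underlying full link totals were never published), so
this construction is validated by simulation instead: on null link graphs
the two-sided rejection rate at α = 0.05 sits inside binomial 99% bounds
of 0.05, and a planted 5× edge excess is recovered as the smallest-p,
flagged pair in ≥ 95% of replicates. Directional *flagging* (observed >
expected **and** p < α) necessarily fires at about α/2 under the null —
the factor-two difference between "rejection rate" and "flag rate" is a
symmetry fact, not a bug.

A locus mapped in both crosses (the real data's Cia13) is carried once
per cross and never paired with itself. Raw p-values drive flagging, to
mirror the original unadjusted analysis; Holm-adjusted values are
reported alongside. Pairs with α ≤ p < 0.06 are reported as near-misses
(the original study retained a pair at p = 0.054).

Degenerate case: with a single admissible QTL pair every margin but `a`
is zero; since the null then predicts the observation with certainty, the
pair is reported with chi-square 0 and p = 1 rather than as untestable.

## The synthetic world

Generator defaults emulate the real study's scale: 20 chromosomes of
125 Mb (~2.5 Gb), 2403 uniformly placed genes, 49 keywords, two crosses
with 5 and 9 QTLs whose union covers 50% ± 5 pp of the genome (QTL
lengths are rescaled iteratively until the realized union coverage hits
the band; a coverage target of exactly 1 tiles whole chromosomes). One
cross-B QTL is deliberately placed overlapping a cross-A QTL, mirroring
real QTL maps (skipped near full coverage, where overlap is forced
anyway).

Choices where no source value exists, fixed once:

* **Keyword weights** are `100 × Beta(0.8, 3)` (mean ≈ 21, skewed low),
  derived from fabricated co-occurrence counts so the raw-count file and
  the weight file are exactly consistent. Real relevance indices are
  likely even more skewed; the flatter choice populates all seven score
  strata, which the calibration tests need.
* **Baseline keyword rate** 0.03 per keyword per gene: mean ≈ 1.5
  matched keywords per gene, ~22% of genes score 0 (and are filtered),
  and the score range spans all bins up to 200+.
* **Record text** is a shuffled bag of filler tokens from a fixed shipped
  word list plus the included keyword terms; filler count 30–70 per
  record (reduced to 10–25 in simulation-heavy tests purely for speed —
  text length does not enter any tested distribution, since scoring is
  presence-based).
* **Links**: `edge_count` (default 300) distinct undirected cross-cross
  gene pairs, sampled with weight 1 times any configured per-QTL-pair
  excess. 300 gives per-pair counts comparable to the published pair
  table (single digits to low twenties).

What the generator does **not** emulate: real gene-density variation,
chromosome-length heterogeneity, correlated keyword usage (keywords are
conditionally independent given position), directed or degree-skewed
hyperlink structure, and real OMIM prose. A green calibration test
therefore establishes that the statistics behave correctly under the
stated independence null — not that real OMIM text satisfies that null.

### Designating the planted pair

With overlapping QTLs, a planted edge excess between one QTL pair is
*genuinely shared* by every pair containing the same genes — a QTL that
nearly contains another inherits its signal. "The designated pair attains
the smallest p" is therefore only a well-posed power criterion for a pair
whose member QTLs share no genes with other QTLs. `designate_clean_pair()`
picks that pair deterministically (largest such pair by gene-count
product). In measured prototypes the distinction is dramatic: top-hit
power 0.99 for a clean pair versus 0.32 for an arbitrary median-size pair
— with the signal in the latter case correctly attributed to the
overlapping loci as well.

## Numerical and interface choices

* Ties in gene ranking break by ascending symbol; all outputs are
  deterministic given a seed, and one master seed drives independent
  per-stage substreams so stages can be regenerated in isolation.
* Interval work is delegated to GenomicRanges/IRanges on a shared
  chromosome universe; brute-force oracles in the tests are independent
  plain-loop implementations.
* File formats are small header-carrying TSVs (catalog, QTLs, keywords,
  co-occurrence counts, links), JSON-lines for the record corpus, and BED
  (0-based half-open, converted on read) as an alternative catalog input.
  The CLI (`simulate`, `score`, `partition`, `connect`, `report`) reads a
  `key: value` (DCF) config file with command-line flags taking
  precedence; there is no YAML dependency in the stack, and DCF is R's
  native equivalent.
* Empty inputs degrade cleanly: an empty corpus yields an empty report
  and exit code 0; an empty bin is "untestable", not an error; totals
  with a zero margin disable the bin tests.

## Known limitations

* The published pair-level p-values cannot be checked directly (their
  input link totals are unpublished); only the test's null behavior and
  power are validated.
* The per-bin test's conservatism (above) is reproduced, not corrected;
  users wanting calibrated bin p-values should use `variant = "2x2"`.
* Token matching cannot recognize morphological variants ("arthritic"
  does not match "arthritis"); substring mode over-matches instead. The
  original tool's behavior between these two poles is unknown.
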