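---
title: "Multi-source mortality concordance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-source mortality concordance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

No single US data source reliably captures every patient death. Health
systems record in-facility deaths and whatever reaches them afterwards;
the Social Security Administration Death Master File (SSADMF) captures
deaths reported to the SSA, but since November 2011 excludes protected
state records. Studies that take mortality endpoints from a single
electronic health record therefore risk substantial under-ascertainment.
`deathconcord` implements the analysis used to quantify this problem when
two health systems serve the same region: link patients across the two
systems and an SSADMF-style extract, classify every matched patient's
death status by which sources recorded it, measure chance-corrected
agreement, and screen for tell-tale data-quality patterns. Because real
registries cannot be shipped, the package also contains a synthetic cohort
generator with full ground truth, so every stage is testable end to end.

## Record linkage

**Cross-system (A–B) linkage** is deterministic and disjunctive: a record
pair links if an identifier crosswalk lists it, if normalized first name,
last name, gender and birth date all agree exactly, or if the medical
record numbers agree. Normalization (`normalize_name()`) folds diacritics,
uppercases and strips non-letters, so case and punctuation never break a
match; there is no fuzzy string matching beyond that.

**Extract (SSADMF) linkage** uses five keyed hash tokens per record
(`build_tokens()`), HMAC-SHA256 over kind-tagged, separator-joined
normalized fields:

| token | fields |
|-------|--------|
| T1 | last name, first initial, gender, birth date |
| T2 | Soundex(last), Soundex(first), gender, birth date |
| T3 | last name, first name, gender, birth date |
| T4 | SSN, gender, birth date |
| T5 | SSN, first name |

A cluster links to an extract record when **T1 and T2 both** match, or when
**any one of T3, T4, T5** matches. The conjunction T1∧T2 tolerates spelling
variants (via Soundex) without letting either loose token match alone; T4
and T5 carry the SSN and are immune to name noise. The hash is keyed by a
user salt; the contract is determinism plus non-invertibility, and the
concrete function (HMAC-SHA256, 256-bit output) is a configuration-level
choice, not load-bearing for the statistics.

The Soundex encoder implements the American (NARA) rules, including the
two classically mishandled cases: H/W do not separate same-coded
consonants, and the first letter's own class collapses with an immediately
following same-class consonant (PFISTER → P236, ASHCRAFT → A261).

Pairwise links are resolved into person clusters by connected components
(`resolve_clusters()`), i.e. linkage is transitive and conflicts merge by
union; the function reports clusters holding several records from one
source, since union merging is exactly where similar-name false linkage
would surface. The extract is linked against already-merged A–B clusters
rather than against raw records — an explicit design choice (the
alternative, record-level linkage, differs only when A and B disagree on
identity fields). Clusters with at least one record from each health
system form the **matched cohort**; everything downstream is computed on
it.

## Concordance classification and summaries

Each matched cluster gets a per-source death-status vector: a source is
"dead" iff any member record from that source carries a death date; with
several dates within one source the earliest is kept and the multiplicity
flagged. The boolean triple maps to one of eight mutually exclusive
categories (all three sources; the three pairs; the three singletons;
none). Summaries derive the union of deaths (cohort minus `none`),
per-source totals, and every percentage in printed style: **half-up
rounding to two decimals**, with both denominators emitted and labelled
(cohort-share percentages use the matched-cohort size; union-share
percentages and source contributions use the union of deaths). The seven
Venn region counts are exported as a labelled vector; drawing the diagram
is left to the caller.

## Fleiss kappa

The three sources are treated as three raters assigning dead / not dead.
For a subject rated "dead" by $k$ of $n = 3$ raters, per-subject agreement
is the fraction of concordant rater pairs,

$$P_i = \frac{k(k-1) + (n-k)(n-k-1)}{n(n-1)},$$

so $P_i = 1$ at unanimity and $1/3$ otherwise. Observed agreement
$\bar P$ is the mean $P_i$; expected agreement uses the pooled marginal
proportion of "dead" assignments $\bar p$, $P_e = \bar p^2 + (1-\bar p)^2$;
and $\kappa = (\bar P - P_e)/(1 - P_e)$. All of this is computed directly
from the aggregated 8-category counts, which is algebraically identical to
expanding one row per subject (a brute-force expansion oracle verifies the
identity to 1e-12 in the tests). When $P_e = 1$ (a single category used by
every rater everywhere) kappa is undefined and the package raises an error
rather than returning a number.

Two observed-agreement definitions coexist in this analysis tradition:
the standard Fleiss mean pairwise agreement, and the proportion of
subjects on whom all three sources concur (`p_all_concur`). Both are
always reported; the standard $\bar P$ feeds the kappa ratio by default
and `observed = "all-concur"` switches the numerator. On the published
category table of the motivating study the two give $\kappa \approx +0.178$
and $\approx -0.233$ respectively, while the study itself prints
$\kappa = -0.312$ with observed agreement 0.9771 — neither variant (nor
any standard Fleiss computation we know of) recovers those printed values
from the printed table, so the package documents the discrepancy instead
of targeting it.

**The kappa paradox.** With death prevalence below 2%, chance agreement on
"not dead" is enormous ($P_e \approx 0.98$), and kappa becomes violently
sensitive to the discordance structure: holding the discordant counts
fixed and growing the unanimous-not-dead mass drives $P_e \to 1$ and moves
kappa monotonically away from zero (a tested invariant). Kappa should
therefore not be read as a standalone quality measure here; the category
table and Venn regions carry the interpretable signal.

**Confidence intervals.** Default is the asymptotic Fleiss–Nee–Landis
standard error for overall kappa,
$\mathrm{SE} = \sqrt{\tfrac{2}{Nn(n-1)}}\,
\frac{\sqrt{(\sum_j p_j q_j)^2 - \sum_j p_j q_j (q_j - p_j)}}{\sum_j p_j q_j}$,
with normal quantiles. A percentile bootstrap over multinomial subject
resampling is available (`ci_method = "bootstrap"`, at least 200
replicates, deterministic given a seed); a simulation test checks that
500-subject bootstrap intervals cover the generating-process kappa in at
least 90 of 100 replicate runs.

## Quality detectors

* **Date discrepancies** (`detect_date_discrepancies()`): for each source
  pair with both death dates present, the whole-calendar-month difference
  is computed; an incomplete final month does not count (Mar 10 to Apr 9
  is 0 months). The operative threshold is **at least one whole month** —
  the published summaries have minima of exactly 1 month, which fixes the
  reading of "more than 1 month" in the study's methods prose. Medians
  over an even count are the mean of the central pair.
* **Lost contact** (`detect_lost_contact()`): a matched cluster is flagged
  for facility X when no X encounter follows the last X visit for 12
  months and the other facility sees the patient strictly after that
  window. A last visit within 12 months of the study end cannot be
  evaluated and is counted as censored, not flagged. One flag per
  (cluster, facility): the detector counts patients, not encounters.
* **Post-death encounters** (`detect_postdeath_encounters()`): for each
  source-specific recorded death date, any encounter at either health
  system strictly more than 365 days later flags the (cluster, death
  source) pair. "More than one year" is read as a strict 365-day offset,
  leap years not special-cased — the simplest defensible rule, and
  configurable. Rates are reported per death source against that source's
  death total.

All three thresholds are monotone by construction (raising any threshold
can only drop flags), and this is tested as a property.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: two patient populations
overlapping in a matched cohort, per-source death capture with a
configurable 8-category overlap structure (exact counts, or independent
per-source rates defaulting to the matched-cohort capture rates 1.62%,
0.44%, 0.59% over the 2007-01-01 to 2020-07-10 window), identity noise
(single-character name typos, missing SSN/MRN), cross-source death-date
shifts, and per-person Poisson encounter streams (mean 4 extra visits per
facility over the window — the study does not state encounter frequency,
so this is the package's own choice of a plausible outpatient volume).
Names come from packaged frequency pools with Zipf weights, so generation
is network-free and seed-reproducible; byte-identical output for identical
config and seed is a tested contract.

Several generator choices exist purely to make ground truth exact rather
than statistical, so detector tests can assert set equality instead of
rates:

* identity keys (surname, first initial, gender, birth date) are unique
  across persons — within colliding name groups, birth dates are drawn
  without replacement — so clean-data linkage has a well-defined truth
  with precision = recall = 1;
* non-designated matched persons end care with a synchronized final visit
  at both facilities, and encounters never extend past the true death
  date, so no accidental lost-contact or post-death patterns arise;
* designated lost-contact persons get a last visit at the lost facility at
  least 25 months before study end and a retained-facility visit strictly
  after the 13th month;
* designated post-death encounters are written to both systems on one
  date more than a year after death (which also keeps the two facilities'
  last visits synchronized);
* designated date shifts move the recorded date in one randomly chosen
  recording source later by a whole number of months (default geometric,
  median 2 months, capped at 122), with the death date resampled early
  enough to stay inside the window and day-of-month capped at 28 so
  end-of-month clipping never eats a month.

What the generator does **not** emulate: demographic correlation
structure, geography, family clustering, realistic survival curves,
duplicate registrations inside one system, or measurement error in birth
dates. Passing tests on synthetic data therefore validate the *logic* of
linkage, classification, agreement and flagging — they say nothing about
real-world linkage sensitivity, where identity noise is richer than
single-character typos.

## Numerical choices and degenerate inputs

* Percentages: half-up rounding at two decimals (base `round()` is
  round-half-even and disagrees on printed values like 20.065).
* Month arithmetic: calendar months with day-of-month clipping
  (`add_months()`), symmetric whole-month distance (`month_delta()`).
* Earliest date wins within a source; multiplicity is flagged, not lost.
* Empty registries, duplicate record ids within a source, malformed
  crosswalk rows, categories that do not sum to the cohort, probabilities
  outside [0, 1], and undefined kappa all raise immediate errors naming
  the offending input.
* Unknown gender is a first-class value "U" and tokens are still emitted.

## Problem sizes in the test suite

The acceptance tests reproduce the published category table on the full
904,581-subject cohort end to end (a few minutes on one CPU); linkage
recovery runs at 10,000 matched + 5,000 single-system patients; detector
ground-truth checks at 5,000; kappa oracle equivalence at up to 10,000
subjects per table; bootstrap calibration at 500 subjects x 100
replicates. These sizes were chosen to keep the default suite fast while
still exercising every full-scale code path.

## Limitations

* Linkage is deterministic; there is no probabilistic (Fellegi–Sunter)
  weighting, and no string-distance matching beyond Soundex.
* The kappa confidence interval uses the overall-kappa variance formula;
  per-category variances are not reported.
* The extract-vs-cluster linkage order is an assumption (see above).
* The printed agreement statistics of the motivating study are not
  recoverable from its printed table; this package reproduces the table
  and everything derivable from it, and documents the rest.
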