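---
title: "Mining acupoint prescriptions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining acupoint prescriptions: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acumine)
```

## The data model

Evidence-synthesis studies of acupuncture therapy reduce each eligible
clinical trial to a *prescription*: the set of acupoints the trial
stimulated. `acumine` treats a collection of prescriptions as market-basket
transactions — `transactions()` holds one set of acupoint codes per study,
equivalent to a 0/1 incidence matrix (`to_incidence_matrix()`) with one row
per trial and one column per acupoint. Codes are compared
case-insensitively after trimming; meridian-style codes (letters + number)
are canonicalised to upper case while named experience points (extra-
meridian acupoints such as Xiongtong) keep their spelling. An
`acu_registry` maps codes to their meridians; strict validation rejects
unknown codes, while permissive mode auto-registers them with meridian
`NONE` so the pipeline can be reused on new extractions.

Two deterministic ordering rules make every tabular output reproducible:
the item universe is ordered by descending frequency with lexicographic
tie-breaks, and mined rules sort by antecedent size, support, confidence,
then codes.

## Frequency analysis

`acupoint_frequency()` counts, for each acupoint, the prescriptions that
contain it; shares are percentages of the *total number of usages* (for the
CSAP reference data, 130), the convention under which the most-used
acupoint PC6 has share 25/130 = 19.2%. All displayed percentages are
rounded half-up on the exact integer ratio at the displayed precision —
never on an intermediate double — which is what reproduces values such as
19.2, 93.75 and a lift of 1.01 (= 405/400 = 1.0125 rounded at two
decimals) bit-for-bit.

`meridian_frequency()` exposes two counting modes because published
meridian tables do not always state theirs: `usage_sum` (sum of member
acupoint usage counts; conserves the usage total) and `prescription_count`
(trials using at least one acupoint of the meridian; bounded by N).
Notably, the published CSAP meridian table is consistent with *neither*
mode applied to the published acupoint table (the pericardium meridian is
printed with frequency 16 although PC6 alone appears 25 times), and its
derivation is not stated. The package therefore computes both transparent
semantics and makes no attempt to reproduce those printed counts; only the
table's internal share arithmetic (16/80 = 20.0%) is asserted in tests.

## Association rules

`frequent_itemsets()` is a textbook Apriori: level-wise candidate
generation (joining sets that share a prefix), pruning any candidate with
an infrequent subset, and support counting against the incidence matrix.
`generate_rules()` then emits, for every frequent antecedent *A* and every
single consequent *b ∉ A*, the rule *A → b* whenever its confidence
σ(A∪b)/σ(A) meets the floor. Consequents are single acupoints, the
behaviour of the SPSS Modeler Apriori node used in the published analysis
and consistent with every published rule row.

Threshold semantics deserve care. The study's floors are 15% minimum
support and 80% minimum confidence, with rules of at most 3 items; these
are the package defaults. The support *column* of published acupoint rule
tables, however, follows the SPSS convention of reporting the
**antecedent** support σ(A)/N — the top published rule LU9 → PC6 prints
59.26% = 16/27 = σ(LU9)/N, not σ(LU9∪PC6)/N = 55.56%. The textbook
joint-support formula is available under `support_convention = "joint"`;
the convention changes only the reported column, never rule eligibility.
Thresholds are compared on exact rationals (`100·count ≥ pct·denominator`),
so a 15% floor on N = 27 means a count of at least 4.05, i.e. 5.

`rule_statistics()` computes the four quantities for any single pair, and
`brute_force_rules()` re-mines by exhaustive enumeration. The two mining
routes are algorithmically independent (level-wise pruning vs. direct
subset enumeration) and the test suite requires exact agreement — ordering,
counts and rounded statistics — across one hundred seeded random datasets
as well as the reference data.

The default `max_rule_size = 3` reproduces the published reporting scope:
the published table contains no rule with more than three items, although
e.g. {LU6, LU9, PC6} → HT5 would pass both floors. Similarly, three rules
that the published counts force above both floors — HT5 → LU6 (the mirror
of the published LU6 → HT5 row, with identical statistics),
{LU6, PC6} → LU9 and {HT5, PC6} → LU6 — are absent from the published
table, which states no deduplication rule. The miner reports them, and
`csap_reference_rules()` flags them `in_published_table = FALSE` rather
than suppressing them silently. Published rule rows list their items in an
order that is not a reliable antecedent/consequent encoding (some rows are
consequent-first), so the reference table stores the statistic-consistent
assignment and all matching is by (antecedent set, consequent).

## Co-occurrence and the co-usage network

`cooccurrence_matrix()` is the cross-product of the incidence matrix:
symmetric joint counts with acupoint frequencies on the diagonal,
normalized as percentages of N (the base under which the top CSAP pair
LU9–PC6 sits at 15/27 = 55.6%, above the 50% mark). No usage-based
normalization is offered; one unambiguous meaning is worth more than a
flag.

`build_network()` connects acupoints used together in at least
`min_weight` prescriptions, weighting edges by the co-occurrence count —
the only symmetric pairwise quantity the pipeline defines. The graph is
**undirected**: co-usage is a symmetric relation, and a single per-node
degree is what core/hub analysis needs. (The original description of the
method says "directed", but nothing downstream of it uses direction.)
Path statistics (`graph_stats()`) are unweighted breadth-first-search
shortest paths; on disconnected graphs they are computed on the largest
connected component and the result records that convention — the common
graph-GUI behaviour. A single-node component reports `NA` path statistics
rather than raising.

`core_decomposition()` implements standard k-core peeling: repeatedly
remove the minimum-degree node, ties broken lexicographically by code;
a node's core number is the running maximum degree at its removal. Core
numbers are invariant to the peeling order — the tie-break only fixes the
order itself — and the tests require agreement with both a naive
recompute-from-scratch fixed point and `igraph::coreness()`.
`fr_layout()` wraps the igraph Fruchterman–Reingold implementation behind
a seed and a bounding frame so identical seeds give identical coordinates.

The published *global* network figures could not be made acceptance
anchors: they are internally inconsistent (36 nodes with 277 edges gives
average degree 2·277/36 ≈ 15.4, yet 23.3 is printed) and the edge
construction step ("association rules flow" weights) is not reconstructible
from printed data. The package asserts structural properties instead:
oracle-equality of path and core statistics, degree/edge conservation, and
a hub-dominated reference network (diameter ≤ 3, PC6 of maximal degree).

## The reconstructed reference dataset

The CSAP study deposited no raw transactions, but for every statistic this
package computes the printed tables pin the data down: N = 27; all 37
acupoint marginals (sum 130); and, from each published rule row, a joint
count — antecedent frequency × confidence, e.g. confidence 93.75% on
σ(LU9) = 16 forces σ(LU9 ∩ PC6) = 15. Set algebra extends these (LU6's
100%-confidence rules make LU6 ⊆ LU9 ∩ PC6, so σ(LU6∩LU9∩HT5) =
σ(LU6∩HT5) = 4). Conversely, every rule *not* in the published table must
stay below the 80% trigger, which yields upper bounds ("guards") such as
σ(BL15 ∩ LU9) ≤ 5 and σ(HT7 ∩ X) ≤ 4 for X ≠ PC6.

`build_csap_fixture()` is one satisfying assignment, constructed once and
frozen in code rather than solved for at runtime — determinism and fast
tests over generality. Free choices (the placement of low-frequency
acupoints) were used to balance prescription sizes around the 130/27 ≈ 4.8
average and to keep every acupoint except the experience point in at least
one prescription with the PC6 hub, so the co-usage network is
hub-dominated. `verify_fixture()` re-checks every marginal, joint and
guard and re-mines the rule table against the reference rows; the result is
a violation report (data, not exceptions), empty for the shipped fixture.
The same dataset ships as a long-format CSV under `inst/extdata/`.

What the fixture does *not* claim: it is constraint-equivalent to the
historical data for every statistic above, but it is not the historical 27
prescriptions, and joint structure the study never printed (most cells of
its co-occurrence heat map, the exact edge weights behind its network
figures) is unknowable from the publication. Conclusions drawn from the
fixture beyond the printed constraints are properties of the
reconstruction, not of the original trials.

## The random-transaction generator

`random_dataset()` draws each item into each transaction independently
(Bernoulli, per-item probability), re-drawing empty transactions, under a
fixed seed. It emulates the *shape* of prescription data — sparse sets
over a modest universe — but none of its dependence structure, so it is
used for property tests (miner-equals-oracle, lift calibration), not for
scientific claims. One subtlety: re-drawing empties conditions the margins
on non-emptiness, which induces mild negative dependence; with only two
items at p = 0.6 and 0.5 the true lift is 0.8, not 1. Independence checks
therefore include low-probability filler items so that empty draws are
rare (true lift ≈ 0.98), the regime in which the empirical lift of an
independent pair lands within ±0.1 of 1 at 2000 transactions.

## Problem sizes and runtime choices

The property suites run at sizes chosen to exercise the algorithms while
keeping the full test run in seconds: one hundred seeded datasets of 5–9
items × 20–30 transactions for miner/oracle equality (small enough for
exhaustive enumeration to be trustworthy and fast), 12–14-node random
graphs for path/core oracles, and a single n = 2000 run for lift
calibration. `brute_force_rules()` refuses universes above 20 items unless
explicitly overridden, since enumeration grows exponentially.

## Known limitations

* The analysis operates on extracted prescription sets only: it does not
  parse trial reports, weight trials by size or quality, or model dosage,
  stimulation mode or treatment schedules.
* Meridian-level counts depend on the chosen mode (see above); published
  meridian frequencies for the reference study are reproducible under
  neither and are not asserted.
* Lift on near-universal items (PC6 in 25/27 prescriptions) is necessarily
  close to 1 and carries little discriminative information; the package
  reports it but draws no significance claims — no interestingness measures
  beyond support/confidence/lift, and no inference, are implemented.
* Layout coordinates are reproducible for a given igraph version but are
  not meaningful beyond display.
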