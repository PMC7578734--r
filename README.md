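# acumine

Association-rule and network mining of acupoint prescriptions.

Evidence-synthesis studies of acupuncture extract, from each eligible
clinical trial, the *prescription* — the set of acupoints the trial
stimulated — and ask which acupoints and which combinations carry the
therapy. `acumine` implements that analysis pipeline for prescription
transaction data, with the acupuncture evidence base for chronic stable
angina pectoris (CSAP) as its built-in reference case:

* **Frequency analysis** — acupoint and meridian usage tables with share
  percentages.
* **Association-rule mining** — an Apriori miner over prescription
  transactions. For an antecedent itemset *A* and a single consequent
  acupoint *b*, with σ(·) the number of prescriptions containing an itemset
  and *N* the number of prescriptions:

  - support `s(A) = σ(A)/N` (rules report either the antecedent support
    `σ(A)/N` — the SPSS-Modeler convention used in published acupoint rule
    tables — or the joint support `σ(A∪b)/N`, selectable);
  - confidence `c(A→b) = σ(A∪b)/σ(A)`;
  - lift `c(A→b) / s(b)`, where lift > 1 indicates the acupoints are used
    together more than independence predicts.

  All statistics are computed on exact integer ratios and rounded half-up
  at the reported precision. An exhaustive-enumeration miner
  (`brute_force_rules()`) ships alongside as an independent oracle.
* **Co-occurrence analysis** — symmetric acupoint × acupoint joint-count
  matrices, normalized by *N*.
* **Network analysis** — the weighted undirected co-usage graph, global
  statistics (average degree, BFS path length, diameter), k-core
  decomposition by iterative peeling, and a seeded Fruchterman–Reingold
  layout with Gephi-style node/edge list export.
* **Reference dataset** — the CSAP study deposited no raw data, but its
  printed tables constrain it tightly: 37 acupoint marginals summing to 130
  usages over *N* = 27 prescriptions, and a joint count for every published
  rule row (antecedent frequency × confidence). `build_csap_fixture()`
  reconstructs a 27-prescription dataset satisfying every one of those
  constraints exactly; `verify_fixture()` re-checks them all and re-mines
  the rule table. `random_dataset()` generates seeded Bernoulli transaction
  data for property testing.

## Worked example

```r
library(acumine)

fx <- build_csap_fixture()
fx
#> Prescription transactions: N = 27 | items = 37 | total usages = 130
#> Top items: PC6, LU9, ST36, BL15, HT7

head(acupoint_frequency(fx), 5)
#>  code frequency share_pct
#>   PC6        25      19.2
#>   LU9        16      12.3
#>  ST36         9       6.9
#>  BL15         7       5.4
#>   HT7         6       4.6

mine_rules(fx)   # defaults: support >= 15%, confidence >= 80%, <= 3 items
#> Association rules: 16 rule(s) | min support 15% (antecedent convention) | ...
#>            rule support confidence lift frequency
#>      LU9 -> PC6   59.26      93.75 1.01        16
#>     ST36 -> PC6   33.33      88.89 0.96         9
#>     BL15 -> PC6   25.93     100.00 1.08         7
#>      HT7 -> PC6   22.22     100.00 1.08         6
#>      ...
```

PC6 (Neiguan) dominates: it appears in 25 of 27 prescriptions (19.2% of
the 130 acupoint usages), and the strongest pairing is LU9 with PC6 —
confidence 93.75% means 15 of the 16 LU9 prescriptions also use PC6, and
lift 1.01 means that pairing sits at about the rate independence would
predict, because PC6 is nearly universal. The high-lift rules (LU6 → HT5,
lift 4.32) mark genuinely selective combinations. Thirteen of the sixteen
mined rules are the published rule table; the remaining three (e.g.
HT5 → LU6) are forced above both thresholds by the same printed counts but
were omitted from the published table — `csap_reference_rules()` lists both
groups explicitly.

```r
top_pairs(cooccurrence_matrix(fx), 1)
#>   item1 item2 count normalized_pct
#> 1   LU9   PC6    15           55.6

graph_stats(build_network(fx))
#> Co-usage network statistics
#>   nodes: 37 | edges: 152 | average degree: 8.22
#>   average path length: 1.793 | diameter: 3 ...
```

The full pipeline — frequency tables, rule table, co-occurrence matrices,
network statistics and node/edge exports, plus a run manifest — is one
call:

```r
run_pipeline(pipeline_config(fx, out_dir = "csap_out"))
```

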