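---
title: "Ingredient co-occurrence networks: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ingredient co-occurrence networks: models, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`coocnet` screens product–ingredient tables for ingredient pairs that
are used together far more often than their individual prevalences
explain, and studies the resulting network. This vignette is the
package's own account of the statistical model, the tunable
parameters, the numerical choices, and what the synthetic benchmark
does and does not establish.

## The screening model

The unit of analysis is one product type (e-liquids, disposables,
rechargeables, refillables — the four notification categories that
contain liquid). For a type with $n$ products, each ingredient is a
binary presence column, and each unordered pair $(i, j)$ has the 2×2
table

|        | $j$ present | $j$ absent |
|--------|-------------|------------|
| $i$ present | $a$ | $b$ |
| $i$ absent  | $c$ | $d$ |

with $n = a+b+c+d$. Two odds-ratio estimators are available:

* **sample**: $\widehat{OR} = ad/bc$, with $\infty$ when $bc = 0$ and
  $ad > 0$, and undefined (reported `NA`) when both products vanish.
* **conditional MLE** (default): the $\psi$ maximizing the noncentral
  hypergeometric likelihood of $a$ with both margins fixed — the
  estimate Fisher's exact test reports. The two differ noticeably in
  small tables (for $a,d = 20$, $b,c = 5$ the sample OR is 16 while
  the CMLE is ≈ 14.8) but agree closely at the large counts the
  significance rule requires, so the significant set is robust to the
  choice. The sample estimator is available for speed and
  transparency.

A pair is significant iff
$a \ge \max(\lceil f \cdot n\rceil, c_{\min})$ **and**
$\widehat{OR} \ge OR_{\min}$, with defaults $f = 0.03$,
$c_{\min} = 10$, $OR_{\min} = 10$. Infinite odds ratios pass the OR
arm: a zero off-diagonal cell at a qualifying count is extreme
overrepresentation, not missing data. Exact-test p-values are computed
for inspection but never enter the verdict — the rule is deliberately
threshold-based, and no multiple-testing correction is applied;
false-positive control comes from the permutation null below.

Two "at least" phrases are interpreted with the ceiling convention:
"at least 3% of products" means $a \ge \lceil 0.03\,n \rceil$, and the
1% prevalence filter keeps an ingredient iff its count reaches
$\lceil 0.01\,n_t \rceil$ (and is at least 1) in *some* type $t$.
Ceiling is the only reading under which an integer count can meet a
fractional bound exactly; both fractions are configurable.

## Curation and filtering

Raw exports list the same chemical under several names. Normalization
is trim + case-fold + internal-whitespace collapse; a user-editable
synonym map then folds stereoisomers (L-menthol → menthol), tautomers
(both notified forms of cyclotene), hydrates (citric acid monohydrate
→ citric acid) and hemiacetals (vanillin propylene glycol acetal →
vanillin) onto canonical names. The shipped map covers one worked
example per merge class; a real analysis is expected to extend it,
since no public curation list exists. When merging makes two entries
of one product identical, concentrations are summed (the merged forms
co-exist in one liquid, so the total is the meaningful amount);
missing values count as zero only when at least one value is present.
Curation is idempotent.

Propylene glycol, glycerol and water are excluded as trivially
ubiquitous carriers before matrix construction; their products keep
their (all-zero) rows so $n$ is unaffected. The prevalence filter is
applied once, globally: the kept set is the union over types, and the
same columns are retained in every type's matrix. This gives all
types a shared vocabulary, which the cross-type Venn comparison
requires. Ingredients are *not* filtered by function — nicotine and
other non-flavor ingredients stay in, and indeed the
nicotine–benzoic-acid pair is one of the strongest signals in both
real markets and the synthetic benchmark.

## The permutation null

To gauge how many significant pairs the rule would produce by chance,
each ingredient column is independently permuted across products and
the screen re-run; the count of significant pairs per replicate is the
calibration. Column shuffling preserves exactly the margin the odds
ratio conditions on (each ingredient's prevalence) while destroying
all between-ingredient structure, which matches the stated purpose; a
global bit-reshuffle variant is available behind `scheme = "global"`.
The number of replicates is configurable (default 10 — at market
scale the null is so far from the rule's joint threshold that
replicates are essentially deterministic zeros); the seed is
mandatory, and the RNG protocol (per replicate, per column in order,
`sample.int(n, colsum)`) is documented so an independent
re-implementation can replay it, as one test does.

Counting under the null short-circuits: odds ratios are evaluated only
for pairs already passing the count arm. The rule being a conjunction,
this is exact, and it keeps ten full-scale replicates (33179 × ~190)
in seconds via one sparse cross-product per replicate.

## Network statistics

Significant pairs form a simple undirected graph; ingredients never
significant in any pair do not appear as nodes. Average degree
$2E/V$ is reported both over all nodes and over the largest component
only — published network tables typically use the main component (a
62-node, 214-edge network containing three isolated pairs has overall
average 6.9 but main-component average $2 \cdot 211 / 56 = 7.5$), and
emitting both lets either convention be inspected. The characteristic
path length is the mean unweighted shortest-path length over
*connected* node pairs, the only convention finite on disconnected
graphs; the diameter is the largest finite shortest-path length. Both
are cross-checked against a from-scratch all-pairs BFS oracle in the
tests. The spring layout (Fruchterman–Reingold, fixed seed, centered)
is cosmetic: it places tightly interlinked ingredients near each
other but carries no statistical meaning, and no attempt is made to
reproduce any manually adjusted published layout.

## MCODE clustering

Dense regions are found with a self-contained implementation of the
MCODE algorithm, so the pipeline does not depend on an external
network application: each vertex is weighted by the core number times
the density of the highest k-core of its closed neighborhood;
complexes grow breadth-first from the highest-weighted unvisited seed,
admitting neighbors whose weight is within `node_score_cutoff`
(default 0.2) of the seed's; haircut then keeps the complex's 2-core,
and complexes lacking a `k_core_filter`-core (default 2) are dropped.
Fluff is off by default and, when enabled, is applied before haircut,
following the original algorithm description. Defaults (degree cutoff
2, max depth 100) are the conventional default settings of that
algorithm; because cluster composition is known to be sensitive to
them, all parameters are exposed in the configuration. Complexes are
vertex-disjoint, each induces a connected subgraph, ranking is by
score = density × size, and every tie (seed order, ranking) breaks
lexicographically so results are fully deterministic.

## The synthetic generator

Confidential notification data cannot ship with the package, so the
generator emulates the market the pipeline targets: four product
types with default counts 33179 / 10970 / 248 / 51 (scalable by one
factor), 194 analyzable ingredients plus 30 deliberately rare ones
(default presence probability 0.002, placed below the 1% filter in
the large types — though the 51-product type's ceiling threshold of 1
lets occasional rare survivors through, which exercises the filter's
"at least one type" clause), and the three always-present carriers.
Ten latent flavor categories each have a disjoint 8-ingredient
signature; a product draws one category and carries each of its
signature ingredients with probability 0.6, every other flavoring
with 0.01. Nicotine appears at prevalence 0.8 and benzoic acid at 0.5
conditional on nicotine, planting the protonation pair. Expected
flavorings per product ≈ 8·0.6 + 184·0.01 + extras ≈ 7, consistent
with the ~10 ± 15 reported for real e-liquids (the generator matches
the mean's order, not the heavy skew). A 5% synonym-variant rate and
random casing give the curation stage real work. Concentrations are
lognormal around 0.3 mg/mL (dispersion 1.0 on the log scale),
spanning the 0.03–1.15 mg/mL range typical of flavoring medians —
cosmetic, used only by the summary surface. Everything derives from
one seed; equal configs give byte-identical output.

What passing the benchmark shows: the pipeline detects exactly the
planted block structure (recall ≥ 0.95, precision ≥ 0.99 of
within-signature pairs at a tenth of market scale) and finds nothing
under the null at full scale. What it does not show: real markets
have overlapping, hierarchical flavor categories, ingredient
popularity following heavy-tailed distributions, and correlated
notification artifacts (e.g. one manufacturer's boilerplate recipes).
Signature overlap can be emulated only crudely (signatures are
disjoint by default for clean ground truth), so quantitative recovery
on real data will be worse than on the benchmark; the benchmark
validates correctness of the machinery, not expected field
performance.

## Numerical choices

* **CMLE solve**: the conditional likelihood is log-concave, so the
  MLE is the root of the score equation $E_\psi[A] = a$; it is found
  by `uniroot` in $\log\psi$ with expanding brackets, relative
  tolerance $10^{-8}$, with the conditional mean computed via
  max-shifted exponential weights for stability. Boundary cases:
  $a$ at its conditional maximum → $\infty$; at its minimum → 0;
  single-point support (a zero margin) → `NA`. Tests compare against
  a brute-force likelihood-grid oracle (agreement within $10^{-4}$
  relative on all interior tables with $n \le 10$ and hundreds of
  random tables to $n = 40$) and against `fisher.test`'s estimate
  (within $10^{-3}$, that function's own optimizer tolerance).
* **p-values**: two-sided exact p = sum of hypergeometric point
  probabilities not exceeding the observed one (with the customary
  $1 + 10^{-7}$ tie slack), matching `fisher.test`.
* **Determinism**: all name-dependent orderings (matrix columns, pair
  canonicalization, component and complex tie-breaks) use C-locale
  radix sorting, so results are identical across platforms and
  locale settings.
* **Degenerate inputs**: zero products of a type yield an empty
  matrix, not an error; empty pair sets yield empty networks with
  `NA` path statistics; an all-`NA` concentration vector yields an
  absent median.

## Problem sizes in the shipped checks

The test suite and the acceptance script run the permutation null at
full market scale (33179 products × ~190 ingredients, 10 replicates)
and the recovery benchmark at a 0.1 scale factor (3318 e-liquids),
sizes at which the whole suite completes in about a minute on a
single CPU while still exercising the sparse-matrix fast paths at
realistic dimensions.

## Known limitations

* The synonym map ships with only the four worked merge classes;
  real curation requires a domain-curated list.
* The significance rule is a hard conjunction; pairs just under
  either threshold vanish entirely (no ranking by evidence is
  implied beyond the odds-ratio sort).
* Characteristic path length and average degree conventions differ
  across network tools; both averaging conventions are emitted, but
  only the connected-pairs CPL is computed.
* MCODE micro-variants exist across implementations; fixtures pin
  the behavior documented here (2-core haircut, pre-haircut fluff,
  global visited marking).
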