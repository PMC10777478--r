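# coocnet

Ingredient co-occurrence networks from product notification data.

Regulators collect product composition data for e-cigarettes and
e-liquids at market scale (tens of thousands of notified products, each
listing its ingredients, their function and concentration). Which
flavoring ingredients are deliberately used *together* is invisible in
per-ingredient summaries but shows up clearly as pairwise
co-occurrence. `coocnet` is an R package for analysts of such data: it
turns a tab-delimited product–ingredient export into a network of
significantly co-occurring ingredient pairs, summary network
statistics, densely connected ingredient clusters, and cross
product-type overlap reports. Because real notification data are
business-confidential, the package ships a synthetic-data generator
with planted flavor-category structure so the entire pipeline is
testable and demonstrable end to end.

## Method

For each product type with `n` products, every unordered ingredient
pair `(i, j)` gets a 2×2 contingency table: `a` products contain both,
`b` only `i`, `c` only `j`, `d` neither. Association is measured by the
odds ratio — either the sample form `OR = ad / bc` or (the default) the
conditional maximum-likelihood estimate reported by Fisher's exact
test, i.e. the ψ maximizing the noncentral hypergeometric likelihood of
`a` given both margins. A pair is **significant** when

    a ≥ max( ⌈0.03 · n⌉ , 10 )   and   OR ≥ 10

— at least 3% of the products and at least 10 products, whichever is
larger, with at least tenfold overrepresentation. Exact-test p-values
are reported but deliberately play no role: with ~194 analyzable
ingredients there are 194·193/2 = 18721 candidate pairs, and the
count-plus-odds-ratio rule is calibrated instead by a permutation null
(each ingredient's presence column is shuffled across products,
preserving prevalence while destroying associations; the rule should
then find nothing). Significant pairs form an undirected network whose
statistics (average degree, characteristic path length, diameter)
are reported per component, and whose dense regions are extracted with
an MCODE implementation (k-core-based vertex weighting, seeded
complex expansion, haircut/fluff post-processing). Pair sets from
different product types are compared as Venn-style exact-subset
regions.

Before any of that, ingredient names are curated: trimmed, case-folded
and merged across notification synonyms (stereoisomers, tautomers,
hydrates, hemiacetals), trivially ubiquitous carriers (propylene
glycol, glycerol, water) are excluded, and ingredients used in less
than 1% of every product type are discarded.

## Worked example

```r
library(coocnet)

gen      <- generate_products(synthetic_config(seed = 1, scale = 0.1))
products <- as_product_table(gen$products) |>
  select_liquid_types() |>
  curate_ingredients()
mats <- prevalence_filter(lapply(
  setNames(liquid_types, liquid_types),
  function(ty) build_presence_matrix(products, ty)
))
mats$E_LIQUID
#> <presence_matrix> E_LIQUID: 3318 products x 177 ingredients (25328 presences)

pairs <- find_significant_pairs(mats$E_LIQUID)
sum(pairs$significant)
#> [1] 267
dplyr::filter(pairs, ingredient_i == "benzoic acid", significant)
#>   ingredient_i ingredient_j    a co_fraction odds_ratio significant
#> 1 benzoic acid nicotine     1343       0.405       55.5 TRUE
```

3318 synthetic e-liquids retain 177 of their ingredients after the 1%
filter; 267 of the 15576 candidate pairs pass the significance rule.
The strongest non-flavor pair is nicotine with benzoic acid (its
protonating agent in the generator's planted structure), co-occurring
in 40.5% of products at a conditional-MLE odds ratio of 55.5.

```r
net <- build_network(pairs, product_type = "E_LIQUID")
glance(net)[, 1:4]
#>   n_nodes n_edges avg_neighbors_overall avg_neighbors_main_component
#> 1      82     267                  6.51                         4.75

find_complexes(net)[1:2, c("rank", "seed", "score", "n_nodes")]
#>   rank seed                     score n_nodes
#> 1    1 2,3,5-trimethyl pyrazine     8       8
#> 2    2 alpha-ionone                 8       8

permutation_null(mats$E_LIQUID, n_reps = 5, seed = 99)
#> <null_calibration> 5 x column-permutation replicates (seed 99, estimator cmle)
#> significant pairs per replicate: 0 0 0 0 0
```

The MCODE clusters recover the generator's planted 8-ingredient
flavor-category signatures (score = density × size; a perfect
8-clique scores 8), and the permutation null finds nothing — the
planted associations, not chance, drive the 267 pairs. Against the
generator's ground truth this run attains pair recall 0.95, precision
0.996 and mean best-match cluster Jaccard 0.975
(`evaluate_recovery()`).

`run_pipeline()` wraps all stages (curation → pair screening → null →
network → clusters → overlap → reports) behind one YAML- or
list-driven configuration and writes TSV/SIF/GraphML/JSON reports plus
a run manifest; `inst/scripts/coocnet-pipeline.R` is a thin
command-line wrapper around it.

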