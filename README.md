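# ethnocore

Structural-core analysis of medicinal-plant free lists.

In ethnobotany and ethnobiology, free-list interviews ("Which medicinal
plants do you know?") record, per informant, an ordered list of the plants
they recall. The *structural core* model holds that a small set of plants —
effective, available, used against the common local diseases — is
disproportionately known and recalled first, forming a cultural "basic kit",
while the remaining *satellite* plants are cited rarely and late. `ethnocore`
implements the quantitative side of testing that model:

1. **Cultural salience.** For item *i*, Smith's salience index averages a
   positional score over all *N* informants:

   *S*ᵢ = (1/N) Σⱼ (Lⱼ − rᵢⱼ + 1)/Lⱼ,

   where informant *j* lists *Lⱼ* items and recalls item *i* at position
   *rᵢⱼ* (0 for non-citers). Frequent and early-recalled items score high.

2. **Salience threshold (null-model classification).** The observed ranking
   is compared, rank by rank, with rankings computed on (by default) 1000
   simulated datasets from a null scenario matched on *N*, the item-pool
   size *M*, and the citations per informant, in which every item is
   exchangeable. Each observed rank gets the smaller empirical tail
   probability as its p-value; the **structural core** is the maximal
   salience-ranked prefix that stays significantly *above* the null
   (p < α = 0.05), everything else is satellite.

3. **Core comparison across groups.** Given two groups (two interview
   periods, or adults vs. children), the union of their cores defines a
   binary participants × core-plants matrix; compositional similarity is
   tested on Jaccard dissimilarities with one-factor PERMANOVA
   (pseudo-*F*, *R*², permutation p; exact enumeration when the number of
   distinct relabelings is small), a homogeneity-of-dispersions test
   (PERMDISP with the negative-eigenvalue correction), and PCoA ordination.

4. **Synthetic free lists.** A generator with a planted core (citation
   probabilities `p_core`/`p_sat`, Plackett–Luce recall-order bias) and a
   controllable two-group core overlap supports power and type-I
   calibration studies of the whole pipeline.

## Worked example

Classify a published salience ranking (bundled with the package: a
two-period survey of 49 informants in Vale do Catimbau, NE Brazil, plus an
adults-vs-children contrast) into core and satellites:

```r
library(ethnocore)
tab <- classify_core(published_salience("period2"))
attr(tab, "core_size")
#> [1] 11
head(as.data.frame(tab), 3)
#>   rank      item salience p_value label
#> 1    1    ameixa   0.5347       0  core
#> 2    2   quixaba   0.3373       0  core
#> 3    3 papaconha   0.3193       0  core
```

The core ends at rank 11 ("bom nome", p = 0.0452); rank 12 ("hortelã",
p = 0.0579) is the first non-significant entry and opens the satellites.

End-to-end comparison of two synthetic groups with disjoint planted cores:

```r
x <- simulate_two_groups(two_group_config(synthetic_config(seed = 11),
                                          core_overlap = 0,
                                          group_sizes = c(50, 50)))
run_comparison(x, seed = 42)
#> Structural-core comparison
#>   core size (group1): 8
#>   core size (group2): 8
#>   core union: 16 plants; 100 retained rows (0 dropped)
#> PERMANOVA (one factor, permutation, 999 relabelings)
#>           Df SumOfSqs  MeanSqs pseudo.F      R2 p.value
#> Groups     1 16.25134 16.25134 163.3264 0.62499   0.001
#> Residuals 98  9.75122  0.09950          0.37501
#> Total     99 26.00256                   1.00000
#> Homogeneity of multivariate dispersions
#> Group mean distances to centroid:
#> group1 group2
#> 0.2839 0.2725
#> F = 0.1529, permutation p = 0.717 (999 permutations)
```

Both planted cores of 8 items are recovered exactly; the disjoint
composition shows up as a large between-group effect (R² = 0.62) at the
permutation floor p = 0.001, while the dispersion test finds no
within-group spread difference — the separation is a location effect, not a
variance artifact.

## Package tour

| function | purpose |
|---|---|
| `read_freelists()`, `canonicalize_items()`, `freelist_summary()` | free-list I/O and canonicalization |
| `compute_salience()` | Smith's salience table |
| `null_salience_distribution()`, `salience_pvalues()`, `classify_core()`, `salience_threshold()` | null-model salience threshold |
| `core_matrix()`, `jaccard_distances()`, `permanova()`, `beta_dispersion()`, `pcoa()`, `plot_ordination()` | core-composition comparison |
| `synthetic_config()`, `simulate_freelists()`, `simulate_two_groups()` | synthetic data with planted cores |
| `run_comparison()`, `run_matrix_comparison()`, `write_report()` | end-to-end pipelines and reports |

See `vignettes/structural-core-analysis.Rmd` for the methodological
details and design choices.
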