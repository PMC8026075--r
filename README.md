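# binsimco

Simulation machinery for studying how **base rates** — the marginal
probability of a one in a binary attribute — affect the agreement among
**binary similarity coefficients**.

Analyses of an *n* × *p* binary matrix (patients × symptoms, examinees ×
items, sites × species) often start by reducing it to a *p* × *p*
similarity matrix between attributes. Every such similarity is a function
of the 2×2 contingency quadruple (*a*, *b*, *c*, *d*) of an attribute
pair: *a* positive matches (1,1), *b* and *c* the two mismatch directions,
*d* negative matches (0,0). Dozens of coefficients exist — co-occurrence
measures in [0,1] such as Jaccard *a*/(*a*+*b*+*c*) and simple matching
(*a*+*d*)/*n*, and association measures in [−1,1] built on the determinant
*ad* − *bc*, such as the phi coefficient

φ = (*ad* − *bc*) / √((*a*+*b*)(*a*+*c*)(*b*+*d*)(*c*+*d*)).

Which of them can be used interchangeably depends strongly on the base
rates of the attributes. `binsimco` quantifies this by Monte-Carlo
simulation:

1. **Generate** quadruples from two independent Bernoulli vectors
   (*n* = 2000) at each of 15 base-rate pairs (π₁, π₂) on the grid
   {.1, .3, .5, .7, .9}, 100,000 trials per pair (the quadruple is exactly
   multinomial under independence, so a fast direct sampler is the
   default).
2. **Evaluate** a registry of 71 binary similarity coefficients on every
   quadruple, with a documented policy for undefined values.
3. **Correlate** the coefficients across trials per base-rate pair,
   dropping degenerate columns (at the default design exactly
   Goodman–Kruskal I and Anderberg, leaving 69).
4. **Partition** each correlation matrix into K = 2 clusters by K-median
   (p-median) clustering, maximising Z = Σᵢ max_{j∈Q} s_ij with a
   multistart fast-interchange heuristic (plus an exhaustive oracle).
5. **Compare** the 15 partitions with the Hubert–Arabie adjusted Rand
   index and extract the coefficient subsets that stay co-clustered across
   all base-rate conditions.

## Worked example

A reduced run (10,000 trials per pair instead of 100,000) finishes in
well under a minute:

```r
library(binsimco)
cfg <- experiment_config(
  simulation = simulation_config(trials = 10000, n = 2000, seed = 42),
  k = 2, restarts = 200)
b <- run_experiment(cfg)

length(b$kept)        # 69
b$dropped_global      # "goodman_kruskal1" "anderberg"

tab <- b$exemplar_table
tab[-1] <- round(tab[-1], 4)
tab[c(1, 6, 10, 13, 15),
    c("pair", "phi-jaccard", "phi-sokal_michener", "jaccard-sokal_michener")]
#>     pair phi-jaccard phi-sokal_michener jaccard-sokal_michener
#>  [.1,.1]      0.9734             0.4698                 0.2560
#>  [.3,.3]      0.9068             0.8516                 0.5519
#>  [.5,.5]      0.8152             0.9998                 0.8150
#>  [.7,.7]      0.6807             0.8516                 0.9636
#>  [.9,.9]      0.4221             0.4646                 0.9989
```

Read down the columns: phi and Jaccard agree almost perfectly at low base
rates (r = .97 at [.1,.1]) and drift apart as the base rates grow; Jaccard
and Sokal–Michener (simple matching) do the opposite, nearly
interchangeable at [.9,.9] (r = .9989); phi and Sokal–Michener agree only
near the symmetric [.5,.5] cell (r = .9998). So "which coefficient you
pick doesn't matter" is true or false depending on where your data's base
rates sit.

Partition agreement across base-rate pairs, and the coefficients that
always cluster together:

```r
round(b$ari_matrix[1:4, 1:4], 4)
#>         [.1,.1] [.1,.3] [.1,.5] [.1,.7]
#> [.1,.1]  1.0000  0.9333  0.8059  0.0267
#> [.1,.3]  0.9333  1.0000  0.8705  0.0380
#> [.1,.5]  0.8059  0.8705  1.0000  0.0380
#> [.1,.7]  0.0267  0.0380  0.0380  1.0000

sort(stable_subset_of(b$stability_full, "sokal_michener"))
#> [1] "austin_colwell"  "ct1"             "ct2"             "gower_legendre"
#> [5] "hamann"          "rogers_tanimoto" "sokal_michener"  "sokal_sneath2"
#> [9] "sokal_sneath3"
```

Similar base-rate pairs produce near-identical two-cluster partitions of
the 69 coefficients (ARI ≥ .80), while disparate pairs ([.1,.1] vs
[.1,.7]) agree no better than chance — and the simple-matching family
above stays together under *every* base-rate condition.

Individual pieces are usable on their own: `evaluate_coefficient()` /
`evaluate_all()` for single quadruples, `apply_coefficient()` to build a
similarity matrix from your own binary data, `multistart_kmedian()` /
`brute_force_kmedian()` for clustering any similarity matrix, and
`partition_ari()` / `co_membership_stability()` for comparing partitions.

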