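# fdtraitkit

Trait choice methods for functional diversity in community ecology.

Functional diversity indices — FAD, dendrogram-based FD, Rao's quadratic
entropy Q, functional dispersion FDis — all start from a species-by-trait
matrix, and *which* traits go into that matrix can change the ecological
conclusion. `fdtraitkit` is for ecologists who want that choice to be
explicit and auditable. It provides:

* **Dimensionality estimation** for a quantitative trait matrix: Kaiser's
  rule, Horn's parallel analysis, and an automated scree elbow, with a
  majority consensus.
* **Trait-subset selection** by three matrix-correlation criteria, scored on
  the trait correlation matrix `S` and its submatrices (subset index set
  `κ`, PC index set `G`):
  - RM coefficient: `RM = corr(X, P_k X) = sqrt(tr([S²]_(κ) S_κ⁻¹) / tr(S))`
    (variance retained by the subset; `100·RM²` is % variation explained),
  - Yanai's GCD: `GCD = tr(P_k P_g)/sqrt(kg) = tr([S_{G}]_(κ) S_κ⁻¹)/sqrt(gk)`
    (closeness of the subset's subspace to chosen principal components),
  - RV coefficient: `RV = corr(XX', P_k XX' P_k)` (similarity of the species
    point configurations before/after projection),
  plus the highest-loadings (HL) rule and PC scores as pseudo-traits.
* **Four functional diversity indices** on any trait subset or PC set, with
  Euclidean distances on pool-standardized traits and UPGMA dendrograms.
* **The complete search**: every one of the `2^p − 1` trait combinations is
  scored by the closeness of association (OLS R², "COD") between each index
  and species richness — the benchmark any selection method can be compared
  against — plus a two-way ANOVA with Tukey letter groups for comparing
  methods across datasets.
* **Seeded generators** of trait matrices with planted factor
  dimensionality and community tables with planted richness–diversity
  associations, so the whole pipeline is testable without field data.

## Worked example

```r
library(fdtraitkit)

# a trait table with 4 planted latent dimensions, and communities
# spanning a richness gradient
tm <- simulate_trait_matrix(150, 10, g = 4, loading = 0.8, noise_sd = 0.6,
                            seed = 7)
cm <- simulate_communities(tm, n_communities = 100,
                           richness_range = c(2, 30), seed = 8)

trait_correlation_summary(tm)
#> Trait correlation summary: 45 pairs, 31.1% significant at P <= 0.05

estimate_dimensionality(tm, n_iter = 500, seed = 7)
#> Intrinsic dimensionality estimates
#>   Kaiser's rule:      4
#>   Parallel analysis:  4 (mean of 500 iterations, seed 7)
#>   Scree elbow:        4 (advisory heuristic)
#>   Consensus:          4
```

About a third of trait pairs are significantly correlated, yet all three
stopping rules agree the matrix has four latent dimensions — so four traits
(or four PCs) should span the functional space. Select four traits by the
RM criterion and benchmark against the complete search:

```r
z  <- standardize_traits(tm)
ws <- build_workspace(z)
best_subset(ws, 4, "RM")
#> RM = 0.8087 for {T1, T6, T7, T8} (65.4% of total variation; exhaustive search)

complete_search(tm, cm)
#> Complete search: 1023 trait subsets x 4 indices
#> Best subset per index:
#>  index                subset size       cod          p_bin
#>    FAD        T3;T4;T5;T6;T9    5 0.9247083       P<=1e-20
#>     FD T1;T3;T4;T6;T7;T9;T10    7 0.9896346       P<=1e-20
#>      Q          T1;T3;T9;T10    4 0.4614074 1e-20<P<=1e-11
#>   FDis          T1;T3;T9;T10    4 0.2834560  1e-11<P<=1e-5

run_method(tm, cm, "RM", k = 4)[, c("method", "subset", "index", "cod", "p_bin")]
#>  method      subset index        cod         p_bin
#>      RM T1;T6;T7;T8   FAD 0.91468284      P<=1e-20
#>      RM T1;T6;T7;T8    FD 0.97465973      P<=1e-20
#>      RM T1;T6;T7;T8     Q 0.30861635 1e-11<P<=1e-5
#>      RM T1;T6;T7;T8  FDis 0.06713784  1e-5<P<=0.01
```

Reading the numbers: the four RM-chosen traits retain 65% of total trait
variation and their FAD/FD track richness closely (R² 0.91/0.97), but the
complete-search optimum is always at least as close (e.g. 0.92/0.99) and is
attained by *different* trait combinations — the gap and the disagreement
are exactly what the benchmark is for. Presence-only indices (FAD, FD)
associate far more tightly with richness than abundance-weighted ones
(Q, FDis) under random assembly, as expected.

A thin command-line front end over the same functions ships in
`inst/cli/fdtraitkit` (subcommands `simulate`, `dim`, `select`, `fd`,
`search`, `compare`; CSV in, CSV out).

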