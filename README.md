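# guildshift

Compositional statistical analysis of penile microbiota count tables and
foreskin immune-cell densities, for microbiome researchers studying how
genital bacterial communities organize with age and interact with tissue
immunology.

Uncircumcised adult penile microbiota form two anti-correlated "guilds" —
a skin-associated gram-positive cluster and an anaerobe cluster — while
pediatric communities are diffuse and weakly structured. `guildshift`
implements the full post-sequencing pipeline needed to demonstrate and
quantify that contrast and its immunological correlates:

* **Preprocessing** — frequency/prevalence contaminant flagging against
  negative controls and DNA concentrations (both-modes removal rule),
  read/abundance pruning, genus agglomeration.
* **Compositional geometry** — multiplicative (CZM) zero replacement with
  δ = 0.65/(N+1), centered-log-ratio (CLR) transform, Aitchison PCA with
  group centroids, and permutation-based group-separation testing
  (envfit-style factor fitting on the first two components).
* **Co-occurrence structure** — top-30 Spearman networks with BH-adjusted
  q-values, cross-cohort correlation shifts Δρ = ρ_A − ρ_B, and
  abundance-weighted community **cohesion** C(i) = Σ_j x_ij κ(j) /
  **connectedness** κ(j) (mean positive / negative correlation of taxon j),
  compared by Wilcoxon rank-sum tests.
* **Differential abundance** — Dirichlet Monte-Carlo CLR instances
  (128 replicates, prior 0.5), expected BH-adjusted Wilcoxon p-values, a
  standardized median-ratio effect size, and the strict classification rule
  |effect| > 0.5 and q ≤ 0.001.
* **Microbe–immune associations** — a dual-arm design: penalized spline
  `clr ~ s(marker, k = 3, bs = "cs")` (REML, automatic smooth selection)
  cross-validated against Monte-Carlo CLR Spearman correlation; only
  direction-concordant pairs significant in both arms (FDR ≤ 0.05) are
  reported.
* **Immune densities & demographics** — paired epidermis-vs-dermis and
  unpaired elective-vs-phimosis density comparisons with BH families,
  Kruskal-Wallis age tests, r×c Fisher's exact tests with Monte-Carlo
  fallback.
* **Synthetic cohorts** — a logistic-normal–multinomial simulator with
  plantable guild covariance blocks, paired circumcision shifts, log-linear
  taxon–marker links, phimosis group effects, and spiked contaminants, so
  every stage is validated by planted-structure recovery.

## Worked example

Simulate an adult-like (two guild blocks) and a pediatric-like (diffuse)
cohort at n = 60, then compare their co-occurrence structure:

```r
library(guildshift)

ad <- simulate_cohort(preset_config("adult-like",     n_samples = 60, seed = 7))
pe <- simulate_cohort(preset_config("pediatric-like", n_samples = 60, seed = 7))

ra <- relative_abundance(prune(ad$counts))
rp <- relative_abundance(prune(pe$counts))
net_a <- correlation_network(ra, top_taxa(ra, min(30, ncol(ra))))
net_p <- correlation_network(rp, top_taxa(rp, min(30, ncol(rp))))

cmp <- delta_rho(net_a, net_p)
round(cmp$median_abs_rho, 3)
#>     a     b
#> 0.258 0.107
head(cmp$top_shifts, 3)
#>          taxon_1         taxon_2 rho_a    rho_b delta_rho
#> 1 Staphylococcus   Lactobacillus 0.748 -0.04679     0.794
#> 2 Staphylococcus Corynebacterium 0.681 -0.10709     0.788
#> 3 Staphylococcus   Streptococcus 0.731  0.00522     0.726

conn_a <- connectedness(net_a); conn_p <- connectedness(net_p)
cc <- compare_cohesion(cohesion(ra, conn_a), cohesion(rp, conn_p),
                       conn_a, conn_p)
cc[, c("quantity", "p", "median_a", "median_b")]
#>            quantity        p median_a median_b
#> 1      cohesion_pos 3.56e-21    0.269   0.1263
#> 2      cohesion_neg 3.56e-21   -0.288  -0.1215
#> 3 connectedness_pos 1.30e-14    0.246   0.1219
#> 4 connectedness_neg 1.18e-10   -0.237  -0.0986
```

The structured cohort shows a higher median absolute pairwise correlation
(0.258 vs 0.107), the largest Δρ shifts are guild-membership changes of
*Staphylococcus* (strongly positive with other skin taxa only in the
structured cohort), and both positive and negative cohesion are
significantly stronger — the planted guild organization, recovered by the
pipeline.

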