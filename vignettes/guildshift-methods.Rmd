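---
title: "Methods: compositional co-occurrence analysis of penile microbiota and foreskin immune cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional co-occurrence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildshift)
```

## Scope and model

`guildshift` implements the post-sequencing statistical analysis of a
pediatric/adult penile microbiota study design: 16S genus count tables and
foreskin immune-cell densities go in; contaminant-filtered, pruned genus
tables, co-occurrence network comparisons, Monte-Carlo compositional
differential abundance, dual-arm microbe–immune associations, and
demographic tests come out. Count data are treated as compositions
throughout: inference happens on centered-log-ratio (CLR) coordinates or on
rank statistics, never on raw counts across samples.

The package also ships a generative simulator so every stage can be
validated by planted-structure recovery rather than against unavailable
cohort data.

## The simulator: what it emulates and what it does not

Samples are drawn from a logistic-normal–multinomial model: a latent
log-abundance vector $z \sim \mathcal N(\mu, \Sigma)$ per subject,
proportions $\mathrm{softmax}(z)$, sequencing depth
$\mathrm{round}(\mathrm{Lognormal}(\mu_d, \sigma_d))$, and counts
multinomial at that depth. This is the simplest standard compositional model
in which a block-structured $\Sigma$ can plant "guilds": sets of genera that
co-occur within a block and exclude members of the other block.

Two presets define the study conditions:

* **pediatric-like** — no covariance blocks (diffuse, weakly structured
  communities), depth lognormal with mean 47,743 reads;
* **adult-like** — two anti-correlated blocks (within-block covariance 0.6,
  between-block −0.4) splitting eight skin-associated gram-positive genera
  (*Finegoldia*, *Corynebacterium*, *Anaerococcus*, *Staphylococcus*, …)
  from eight anaerobes (*Prevotella*, *Hoylesella*, *Peptoniphilus*,
  *Porphyromonas*, …), depth mean 190,591 reads.

The depth means match the two cohorts' published sequencing depths; the
lognormal shape (log-sd 0.4) and the graded latent means
($\mu$ from 2.5 down to −2.5 across 30 genera, giving a realistic
rank-abundance curve) are the package's own choices, fixed once — the
published analyses report only depth means, not their dispersion.

Other planted structure: a latent log-abundance shift applied at the post
timepoint of paired samples (subject-level $z$ shared between timepoints);
log-linear marker links
$\mathrm{density} = \exp(a + \sum \mathrm{sign}\cdot\mathrm{strength}\cdot
\mathrm{CLR}(\mathrm{taxon}) + \varepsilon)$ acting in one configurable
tissue compartment (default inner-foreskin dermis, where the study design
localizes its immune associations); multiplicative group effects on
phimosis subjects in that compartment; and spiked contaminants whose
proportion in true samples scales as $1/\mathrm{dna\_conc}$ and whose
presence is sparse (20% of true samples), giving both the frequency- and
prevalence-mode signatures.

The simulator does **not** emulate: taxonomic misassignment, chimeras,
run/batch effects, overdispersion beyond the logistic-normal level,
longitudinal drift, or realistic immune-marker covariance between
compartments. Passing recovery tests therefore demonstrate that the
pipeline detects the modelled structure at study-scale sample sizes, not
that it is robust to every artefact of real amplicon data.

## Preprocessing

* **Contaminant flagging** uses the frequency/prevalence decision
  structure: frequency mode compares, per taxon over samples where it is
  present, a model with log relative abundance proportional to
  $\log(1/\mathrm{dna\_conc})$ (slope fixed at 1) against a constant model
  by a one-sided F-ratio of residual sums of squares; prevalence mode
  scores a 2×2 presence-by-control-status table by one-sided chi-squared.
  These are simplified, fully testable scores with the same decision
  structure as the published tool; only taxa flagged by **both** modes (at
  threshold 0.1) are removed, alongside Eukaryota / Chloroplast /
  Mitochondria lineages.
* **Pruning** drops samples under 1,000 reads first, then taxa whose
  per-sample proportion never reaches 1% in any retained sample. The
  max-per-sample reading of the abundance filter is a deliberate choice:
  a dataset-total reading would remove nearly every taxon.
* **Agglomeration** to genus pools unassigned taxa into
  `unclassified_<parent>` and conserves per-sample totals exactly.

## Compositional geometry

Zeros are replaced multiplicatively (CZM style): each zero in sample $i$
becomes $\delta_i = 0.65/(N_i+1)$, with $N_i$ the sample's total count,
and nonzero parts are rescaled to preserve the unit sum. CLR coordinates
are $\log x_j - \overline{\log x}$; PCA is the SVD of the column-centered
CLR matrix, which is exactly principal coordinates on Aitchison distances
but also yields taxon loadings. Group separation is tested by factor
fitting on the first two components (the plotted space): $r^2 = 1 -
SS_{\mathrm{within}}/SS_{\mathrm{total}}$ with a seeded label-permutation
p-value, default 999 permutations. Whether to fit in 2-D or full space was
an open choice; 2-D matches the displayed ordination and is what the test
asserts.

## Co-occurrence networks, Δρ, cohesion

Networks are Spearman correlations (average ranks) over the top-30 genera
by mean relative abundance, BH-adjusted over the upper triangle only;
zero-variance taxa yield NA pairs excluded from the BH family. Correlations
are computed on relative abundances by default (a CLR input is accepted),
matching the pairing of classical rank correlations with proportional
abundance displays. Cross-cohort restructuring is quantified as
$\Delta\rho = \rho_A - \rho_B$ on shared taxa, with $|\rho|$ and
$\Delta\rho$ distributions compared by Wilcoxon rank-sum tests.

Connectedness and cohesion follow the abundance-weighted mean-correlation
construction: $\kappa_{\mathrm{pos}}(j)$ is the mean positive off-diagonal
correlation of taxon $j$ (0 if none), $\kappa_{\mathrm{neg}}$ its negative
counterpart, and sample cohesion is $C(i) = \sum_j x_{ij}\kappa(j)$ over
re-closed network-taxon abundances. No null-model correction is applied:
the source analyses name the quantities and their ranges but no formula,
and this is the simplest construction consistent with those ranges
($\kappa_{\mathrm{pos}}, C_{\mathrm{pos}} \in [0,1]$;
$\kappa_{\mathrm{neg}}, C_{\mathrm{neg}} \in [-1,0]$).

## Monte-Carlo CLR differential abundance

Per sample, proportions are drawn from $\mathrm{Dirichlet}(counts + 0.5)$
128 times and CLR-transformed. Per instance, a two-sided Wilcoxon rank-sum
test per taxon is BH-adjusted across taxa; `q_expected` is the mean
adjusted p over instances (BH is applied per instance, never to averaged
p-values). The effect size is the pooled median of elementwise ratios
(between-group difference) / max(|within-group difference| per group),
from min(group sizes) random pairings per instance, with pairing indices
drawn independently of label order so that swapping group levels negates
every effect exactly.

This estimator is deliberately *damped* relative to Cohen's d: on normal
populations with unit SD, a latent shift of 1 yields a median effect near
0.62 and a shift of 2 near 1.29 (measured at n = 50/group). That scale is
consistent with published effect magnitudes of this kind (e.g. an effect
of 0.87 accompanying a 3.5%→21.8% median-proportion change), and its null
spread at n = 20/group (SE ≈ 0.2) is the sampling floor of any
location-difference statistic at that size — no estimator on this scale
can keep 95% of null effects inside ±0.3 at n = 20/20, which is why tests
assert null *centring* and zero *classifications* instead. Classification
uses the strict rule |effect| > 0.5 **and** q ≤ 0.001; note the source
tables list two genera at effect −0.49 as significant, an inconsistency
with the stated rule that this package surfaces rather than resolves (the
strict rule is implemented).

The unpaired rank-sum test is the default even for pre/post contrasts,
matching the printed analysis; `paired = TRUE` exposes the signed-rank
alternative.

## Dual-arm microbe–immune associations

Taxa detected in ≥30% of samples are tested against marker densities by
two arms: (i) a penalized spline `clr ~ s(marker, k = 3, bs = "cs")`
fitted by REML with `select = TRUE`, and (ii) Monte-Carlo Spearman
correlation of Dirichlet CLR instances with the marker. BH adjustment is
applied within each arm across the full taxon × marker grid; only pairs
significant in both arms (adjusted p ≤ 0.05) **and** agreeing in direction
(sign of the correlation vs sign of the spline's fitted end-to-end trend)
are reported. The direction check is a deliberate addition — an
intersection rule alone could report a pair significant in opposite
directions — and can be disabled.

A property of the rank-3 shrinkage basis worth knowing: a strongly linear
response is fitted with edf near 2 (both basis functions active, curvature
negligible), so "effectively linear" should be judged from the fitted
curve, not from edf ≈ 1; under independence the double penalty shrinks the
smooth to edf < 0.5. Basis-adequacy diagnostics (k-index) are computed and
reported but never used to drop fits. An alternative basis
(`bs = "cr"` + `select`) does yield edf ≈ 1 in the linear limit but
measurably inflates the null rejection rate of the smooth's p-value
(0.125 vs 0.062 at nominal 0.05 over 400 null fits), so the
better-calibrated shrinkage basis is retained.

## Immune densities and demographics

Densities (cells/mm²) are compared epidermis-vs-dermis with paired
Wilcoxon tests per marker × aspect, and elective-vs-phimosis with unpaired
rank-sum tests per marker × aspect × layer; BH families span all
marker × compartment tests within one comparison type (the widest,
most conservative family, since the source does not define it).
Participants missing a layer are excluded from that paired test with a
message. Age differences use Kruskal-Wallis; ethnicity contingencies use
Fisher's exact test — exact enumeration when feasible, otherwise a seeded
Monte-Carlo estimate (≥ 10⁵ tables) with its standard error reported.

## Numerical choices and degenerate inputs

* All randomness takes an explicit integer seed; RNG state is restored
  after every call, and identical seeds give bit-identical output.
* Block covariance matrices are projected to the nearest PSD matrix by
  eigenvalue clipping at 1e-10.
* A paired Wilcoxon on identical layers (all zero differences) returns
  p = 1 rather than NaN.
* Zero-sum samples are an error everywhere (they should have been pruned),
  as are all-zero composition rows in zero replacement; a replacement
  δ exceeding the smallest observed proportion warns.
* Spearman p-values use the asymptotic t approximation (matching
  `cor.test(..., exact = FALSE)`), which unit tests verify against a
  brute-force rank computation on small tables.
* Strict inequalities: core-taxon detection (("> 1%")) and the
  differential-abundance effect gate (|effect| > 0.5) are strict;
  prevalence ("≥ 50% of samples") and q thresholds are inclusive.

## Problem sizes used in the validation suite

Recovery and calibration tests run at the study's own scale: cohorts of
60 samples for the network contrast, 40 subject pairs for differential
abundance (128 Dirichlet instances), 50 samples for the association arms,
and 200 replicates for each null-calibration check (199 label permutations
per ordination test). These sizes are the package's validation design;
they match the published cohort sizes (75 pediatric / 56 adult
participants, 51 follow-up pairs, 55 in the phimosis contrast) closely
enough that recovery at these sizes is informative about the design.

## Known limitations

* The cohesion/connectedness construction is one documented choice among
  several in the literature (no null-model correction).
* The contaminant scores are simplified relative to the published tool;
  decisions (both-modes intersection at 0.1) are the contract, not score
  equality.
* Effect sizes are not numerically comparable to other tools' effect
  scales (damped, see above).
* The dual-arm association analysis assumes densities are measured on the
  same participants as the microbiota and complete per compartment;
  samples with missing densities are dropped listwise per compartment.
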