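Package: guildshift
Title: Compositional Analysis of Penile Microbiota Co-Occurrence Structure and
    Foreskin Immune-Cell Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-sequencing statistical analysis of 16S rRNA genus count
    tables and tissue immune-cell densities: contaminant flagging against
    negative controls and DNA concentrations, read and abundance pruning,
    genus agglomeration, centered-log-ratio (CLR) workflows with
    multiplicative zero replacement, Aitchison principal-component ordination
    with permutation-based group-separation tests, top-N Spearman
    co-occurrence networks with cross-cohort correlation shifts (delta rho),
    community cohesion and connectedness metrics, Dirichlet Monte-Carlo CLR
    differential abundance and marker correlation, a dual-arm (penalized
    spline plus Monte-Carlo correlation) microbe-immune association pipeline
    reporting only concordant hits, immune-cell density group comparisons,
    and demographic tests. Includes a logistic-normal-multinomial cohort
    simulator with plantable guild covariance blocks, circumcision shifts,
    marker links, and spiked contaminants for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
RoxygenNote: 7.3.3
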