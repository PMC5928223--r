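# fattaste

Linking orosensory fatty-acid detection thresholds to the microbiota and
salivary environment of the circumvallate papillae (CVP).

Some people need a thousand-fold higher concentration of linoleic acid (LA)
than others before they can taste it. `fattaste` implements, as a tested and
reusable R pipeline, the analysis chain used to ask whether this
taster/non-taster phenotype is associated with the oral microbial and
salivary micro-environment:

* **Psychophysics** — the ascending 3-alternative forced-choice (3-AFC)
  staircase over a geometric ladder (default: 18 solutions, 0.00028% to ~5%
  LA wt/wt in 0.25 log10 steps), the
  three-consecutive-correct stop rule, censoring at the series top, and the
  taster/non-taster (T/NT) classification at the 0.5% cutoff.
* **Microbiome feature-table stages** — low-count OTU filtering, taxonomic
  rank aggregation, relative abundance, Shannon diversity, rarefaction,
  Bray-Curtis PCoA ordination, per-taxon covariate regression, and a
  two-class LDA effect-size screen (Kruskal-Wallis alpha 0.05, log10 effect
  cutoff 2.0) for discriminant taxa.
* **Multiblock PLS-DA** — the core statistic. Four predictor blocks
  (biological determinants, stimulated saliva, resting saliva, microbiota
  family abundances) are autoscaled and block-balanced (each block divided
  by the square root of its width, equalising block sums of squares), fitted
  by NIPALS on the concatenated super-matrix, and summarised by per-block
  importances, per-component explained Y variance, variable importance in
  the projection — `VIP_j = sqrt(p Σ_a SSY_a w_ja² / Σ_a SSY_a)`, with
  `Σ VIP² = p` — VIP > 1 selection on component 1, correlation-loading
  display at |r| > 0.3, and unadjusted two-sided Mann-Whitney post-hoc
  tests with `§`/`*`/`**` significance bands.
* **Synthetic cohorts** — a seeded generator
  (Dirichlet-multinomial microbiome at depth 50,000; lognormal saliva and
  clinical variables; thresholds drawn on the ladder) with *planted* effects
  as ground truth, so every stage is testable end to end without subject
  data.

## Worked example

Generate the default cohort (21 normal-weight + 17 obese subjects, non-taster
fractions 4/21 and 8/17, four planted effects) and run the
taster-vs-non-taster discriminant analysis:

```r
library(fattaste)

co  <- generate_cohort(cohort_spec(seed = 1))
fit <- fit_mbpls(co$blocks, co$metadata$group_taste, n_components = 2)
fit
#> MB-PLS-DA model: 38 samples, 41 variables in 4 blocks, 2 components
#>   explained Y variance: 84.9%, 9.6%
#>   block importance (comp 1): biological_determinants 0.11, stimulated_saliva 0.05,
#>                              resting_saliva 0.16, microbiota 0.68

rep <- merge(select_variables(fit),
             mann_whitney_posthoc(co$blocks, co$metadata$group_taste),
             by = c("block", "variable"), sort = FALSE)
head(rep[order(-rep$vip), c("block", "variable", "vip", "loading_comp1",
                            "selected", "p_value", "band")])
#>           block                  variable  vip loading_comp1 selected  p_value band
#>      microbiota            Bacteroidaceae 2.14        -0.937     TRUE 1.04e-06   **
#>      microbiota TM7_family_incertae_sedis 2.05         0.845     TRUE 1.04e-06   **
#>  resting_saliva                    Flux_R 1.74        -0.676     TRUE 3.65e-04   **
#>      microbiota           Lachnospiraceae 1.56         0.736     TRUE 1.18e-05   **
#>      microbiota              unclassified 1.55         0.700     TRUE 4.89e-06   **
#>      microbiota            Prevotellaceae 1.52         0.650     TRUE 7.64e-06   **
```

Reading the output: the first component separates T from NT and explains 85%
of the class variance, with the microbiota block carrying 68% of the
discriminant weight. The planted truth is recovered — TM7 enriched in
tasters (positive loading), Bacteroidaceae and resting salivary flow
(`Flux_R`) higher in non-tasters (negative loadings), all with VIP > 1 and
p < 0.01. Other families (Lachnospiraceae, Prevotellaceae, ...) also rank
highly: planting an 8-fold enrichment in a *composition* necessarily
depresses every other family in that class, so these are real, induced
contrasts, not false positives.

Group thresholds are summarised geometrically:

```r
with(co$metadata, geometric_mean_threshold(la_threshold[group_taste == "T"]))
#> [1] 0.004763512   # % LA wt/wt
```

Cohorts round-trip through TSV (`write_cohort`), and `run_comparison` chains
the full pipeline (classify → diversity → effect-size screen → assemble →
fit → select → post-hoc) for any of the four designs `NW_vs_O`, `T_vs_NT`,
`OT_vs_ONT`, `NWNT_vs_ONT` from a list or YAML config, writing
`diversity.tsv`, `lefse_results.tsv`, `vip_report.tsv` and `summary.json`.

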