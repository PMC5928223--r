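---
title: "Methods: fatty-taste thresholds, papillae microbiota and multiblock PLS-DA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatty-taste thresholds, papillae microbiota and multiblock PLS-DA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Orosensory sensitivity to dietary fat varies widely between people: in an
ascending dilution test of linoleic acid (LA), detection thresholds span
about five orders of magnitude. Subjects whose threshold reaches or exceeds
0.5% LA (wt/wt) are conventionally called non-tasters (NT), the rest tasters
(T). `fattaste` implements the analysis chain that asks whether this
phenotype is associated with the microbial and salivary environment of the
circumvallate papillae (CVP) — the large gustatory papillae at the back of
the tongue — by combining three stages:

1. **Psychophysics** — the three-alternative forced-choice (3-AFC) ascending
   staircase, threshold extraction and T/NT classification;
2. **Microbiome feature-table analysis** — count filtering, rank
   aggregation, relative abundance, Shannon diversity, rarefaction,
   Bray-Curtis principal coordinates, per-taxon covariate regression, and a
   two-class LDA effect-size screen for discriminant taxa;
3. **Multiblock PLS discriminant analysis (MB-PLS-DA)** — the joint model of
   four predictor blocks (clinical determinants, stimulated saliva, resting
   saliva, microbiota families) against a two-class outcome, with
   block-balanced scaling, block importances, VIP-based variable selection
   and Mann-Whitney post-hoc tests.

Because no subject-level data are distributed, a seeded synthetic-cohort
generator with *planted* effects is a first-class part of the package: every
downstream claim is validated as recovery of known ground truth.

# The 3-AFC staircase

```{r}
library(fattaste)
series <- build_concentration_series(c_min = 0.00028, step_log10 = 0.25,
                                     n_steps = 18)
series
```

The ladder is geometric: `c_min * 10^(0.25 k)`, 18 solutions. It is built by
*step count*, not by endpoint, because 18 quarter-log steps from 0.00028%
land at 4.979%, within 0.5% relative of the nominal 5% top solution —
`build_concentration_series` validates nothing beyond positivity and
monotonicity, and the acceptance suite checks the endpoint tolerance.

Per presentation the subject must identify the odd cup among three (chance
1/3). The published stop rule — stop when the sample is "correctly
identified 3 times, consecutively", that concentration being the threshold —
under-determines the presentation schedule. We adopt the only reading under
which the rule denotes a single concentration: after a *correct*
identification the same concentration is presented again; after an
*incorrect* one the staircase advances a step; the threshold is the first
concentration accumulating three consecutive correct sets. In
`detect_threshold` a streak is therefore broken both by an error and by a
concentration change. Subjects who never meet the criterion are *censored*
at the series maximum and classified NT (their true threshold is at or above
the top solution). This convention is a documented choice, not a claim about
the original protocol.

`simulate_3afc_session` models the subject as a step function with guessing:
below the true threshold responses are correct with probability
`guess_rate` (default 1/3), at or above it with probability
`1 - lapse_rate`. With `guess_rate = 0` the simulator is deterministic and
must return the smallest series value at or above the true threshold — the
exactness anchor used in the tests. Guessing biases the staircase downward
(a lucky triple ends the session early); over 1000 simulated sessions the
median detected threshold stays within one series step of the truth, which
is the resolution a quarter-log ladder can support.

Group thresholds are summarised by geometric means
(`geometric_mean_threshold`), the natural location summary for a quantity
spanning decades.

# Microbiome stages

The feature table is a plain samples-by-features integer matrix with an
optional lineage sidecar. Choices that matter:

* **Low-count filter** (`filter_low_count_otus`, default `min_total = 3`):
  the threshold is applied to a feature's *total across all samples*,
  reading the published "OTU with fewer than 3 sequences" rule as a global
  count; a per-sample variant was considered and rejected because the rule
  is phrased about the OTU, not about per-sample cells.
* **Shannon diversity** (`shannon_index`): reported in nats by default; the
  base is an argument because conventions differ and the source analyses do
  not state one.
* **Ordination** (`bray_curtis_pcoa`): the published figures label an
  ambiguous "Principal Component Orthogonal Analysis"; we implement
  Bray-Curtis dissimilarity on relative abundances followed by classical
  metric MDS (PCoA), the standard reading for compositional microbiome
  profiles, with `method = "euclidean"` available as the alternative.
  Negative eigenvalues (Bray-Curtis is non-Euclidean) are excluded from the
  explained-variance denominators.
* **Taxon-covariate regression** (`taxa_covariate_regression`): abundances
  are regressed on BMI untransformed, but on *log10* detection threshold,
  since thresholds are log-distributed across the ladder. Pearson r with its
  t-test p and Spearman's rho are both reported.

## The two-class effect-size screen

`effect_size_lda` is a deliberate two-class, no-subclass reduction of the
LEfSe procedure: per-sample abundances are rescaled to one million, each
taxon is screened by Kruskal-Wallis (alpha 0.05), and surviving taxa get an
effect size equal to the mean over 30 within-class bootstrap rounds of
`log10 |difference of class means|` on the per-million scale, floored at 0,
with the discriminant cutoff at 2.0. The one-vs-all LDA step of the original
tool is replaced by the class-mean contrast — with two classes and no
subclass structure the two agree in scale (a planted contrast of 100,000 vs
10 per million scores ≈ 5; a 50-per-million contrast scores ≈ 1.7 and fails
the 2.0 cutoff). This is an approximation of, not a byte-match to, the
Galaxy implementation.

# The multiblock discriminant model

## Preprocessing

All variables are mean-centred and autoscaled to unit variance; each block
is then divided by the square root of its variable count
(`preprocess_blocks`). After this every block has an identical total sum of
squares, which is precisely the "balanced sum-of-squares contribution"
requirement: the 18-family microbiota block cannot out-vote the 4-variable
clinical block by width alone. Constant columns are an error (they carry no
discriminant information and break autoscaling), as are missing values — the
intended policy is complete-case analysis upstream (`assemble_blocks` drops
subjects missing from any table and logs the count).

## Fitting

`fit_mbpls` fits the super-score form of multiblock PLS: NIPALS on the
preprocessed concatenated matrix. Per component,

* super weight `w = X'u / ||X'u||`, iterated with the Y score `u` to
  convergence (tolerance 1e-12 on the score, 1000 iterations maximum —
  non-convergence is an error, never silent);
* super score `t = X w`; block scores are `X_b w_b / ||w_b||` from the
  partition of `w`;
* deflation `X <- X - t p'` with `p = X't/t't`, and regression deflation of
  Y;
* block importance of block b = `sum(w_b^2)` (the share of squared super
  weight in the block; `||w|| = 1`, so importances sum to 1 per component);
* explained X and Y variance from the sum-of-squares drop under deflation.

The two-class outcome is coded as a single centred indicator column; a
two-column dummy coding is provided and verified to give the same components
up to sign. With a single Y column the NIPALS inner loop converges
immediately, so the fit is deterministic to the bit — there is no random
initialisation anywhere in the model.

A known identity makes this implementation testable from the outside: the
super scores and weights of MB-PLS equal those of ordinary PLS run on the
concatenated preprocessed matrix. The test suite asserts `|r| > 1 - 1e-8`
per component against an independently written textbook NIPALS (and, in a
separate unit test, against `mixOmics::pls`).

## Component and variable selection

* `select_components`: interpret the largest prefix of components each
  explaining at least 10% of Y variance (minimum one). The rule is
  prefix-based: fractions (0.05, 0.3) give one component, because
  interpretation stops at the first weak dimension.
* `vip_scores`: `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with
  unit-norm weights, so `sum_j VIP_j^2 = p` identically — asserted to 1e-8
  on random models. VIP is computed on the first component by default (the
  published selection rule), with the component count as a parameter.
* `select_variables`: a variable is *selected* when VIP > 1 (strict: a VIP
  of exactly 1, the equal-contribution point, is not selected) and
  *displayed* when its maximum absolute correlation loading on components
  1-2 exceeds 0.3. The published ">0.3 loadings weights" phrase is ambiguous
  between raw weights and correlation loadings; we use correlation loadings
  (the quantity bounded in [-1, 1] for which 0.3 is a meaningful display
  cutoff), and the raw weights remain available in the model object.
* `mann_whitney_posthoc`: two-sided rank-sum tests per variable on the raw
  data; exact p when the combined n is at most 20 and tie-free, otherwise
  the tie/continuity-corrected normal approximation. No multiplicity
  adjustment is applied, mirroring the original analysis; bands are
  strict — `**` p<0.01, `*` p<0.05, `§` p<0.1, `ns` otherwise.

# The synthetic cohort generator

`generate_cohort` emulates the study's design, not any particular data set:

* **Design defaults**: 21 normal-weight (BMI uniform on [19, 25)) and 17
  obese (BMI uniform on [30, 45)) subjects; non-taster fractions 4/21 and
  8/17. The published subgroup counts are internally inconsistent (the
  obese T/NT split is reported both as 9/9 and implied 9/8), so all four
  design numbers are parameters, not claims.
* **Thresholds**: tasters draw log-uniformly over the series values below
  the 0.5% cutoff; non-tasters at or above it, with 25% censored at the 5%
  top — the threshold distribution in published cohorts reaches the series
  maximum. Labels are therefore consistent with `classify_taster` by
  construction, and the tests assert it.
* **Microbiota**: per sample a Dirichlet-multinomial draw at depth 50,000
  (the order of the reads retained after QC in the source pipeline). Base
  concentrations encode a tongue-like community (Lachnospiraceae,
  Porphyromonadaceae, Prevotellaceae dominant; TM7 at ~1%) with total
  concentration 200, i.e. clearly overdispersed relative to multinomial
  sampling. A planted effect multiplies the target family's concentration by
  `2^magnitude` in the target class.
* **Saliva/clinical blocks**: lognormal with unit log-SD baselines (all
  Table-style variables are positive flows, concentrations or activities,
  so positivity must hold by construction); planted effects are additive
  shifts of `magnitude` SD on the log scale. Blood LPS additionally carries
  a fixed +0.5 SD (log-scale) elevation in the obese group, reflecting the
  reported direction of that clinical contrast.
* **Default planted truth** (`default_effects`): TM7 +3 log2 in tasters,
  Bacteroidaceae +3 log2 in non-tasters, resting flow +1.5 SD in
  non-tasters, resting lysozyme +1.5 SD in tasters — the directions the
  multivariate analysis is expected to surface.

What the generator does *not* emulate: covariance among saliva variables,
age/BMI structure beyond the group split, OTU-level sequence variation, or
any real-data batch effects. Passing recovery tests therefore demonstrates
that the pipeline detects effects of the stated kind and size under clean
conditions; it does not certify performance on real cohorts.

## A note on compositional nulls

Planting a fold-change in a *composition* necessarily moves every other
family's relative abundance (closure): in a cohort with an 8-fold
Bacteroidaceae enrichment in non-tasters, the other 17 families are all
genuinely depressed in that class. Non-planted microbiota families are
therefore **not** null variables, and null calibration of the selection
rules is asserted over the 21 non-planted saliva/clinical variables, where
exchangeability actually holds.

# Problem sizes and numerical choices

The validation suite runs at the study's own scale: cohorts of 38-40
subjects, depth 50,000, 50 seeds for recovery rates, 100 random models for
the VIP identity, 200-500 seeds for calibration checks — all chosen as the
smallest sizes at which the binomial error bands are informative.
Tolerances: 1e-9 for block balance and distance preservation (pure
algebra), 1e-8 for the PLS oracle identity and VIP normalization
(accumulated floating-point error over deflation), binomial 99-99.9% bands
for all stochastic rates. All randomness flows through explicit seeds;
repeated calls are bitwise identical.

# Known limitations

* The effect-size screen is the two-class reduction; multi-class or
  subclass designs are rejected with an error rather than approximated.
* No cross-validated prediction accuracy or permutation-based model p-value
  is computed for the MB-PLS-DA — the model is used descriptively, as in the
  source analysis; adding validation would be the natural extension.
* Missing data are handled by complete-case subject dropping only.
* The 3-AFC simulator's step-function psychometric model ignores the
  gradual slope of real detection curves; it is designed to make the stop
  rule and its censoring behaviour exactly testable, not to model human
  variability.
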