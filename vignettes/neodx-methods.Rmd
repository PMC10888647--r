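---
title: "Statistical methods behind neodx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind neodx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neodx)
```

# The problem

Neonatal hypoxic–ischemic encephalopathy (HIE) must be diagnosed within a
few hours of birth for therapeutic hypothermia to help, yet it is easily
confused with sepsis and inborn metabolic disorders. Routine newborn
screening already quantifies a fixed panel of 57 low-molecular-weight
compounds — 14 amino acids, 36 acylcarnitines, 2 nucleosides,
succinylacetone and 4 lysophosphatidylcholines — in dried blood spots
(DBS), so a diagnostic signal inside that panel would be immediately
deployable. `neodx` implements the complete statistical pathway from a
samples-by-analytes concentration table (µmol/L) to diagnostic models for
HIE, mirroring the group designs of a Rice–Vannucci neonatal rat study:
a time course (control / 3 h / 6 h post-insult, n = 10/13/12), an
LPS-inflammation arm (n = 11/11/27) and a therapeutic-hypothermia arm
(n = 13/16/14).

An important feature of screening panels is that several isobaric species
are indistinguishable by the assay and are reported under combined codes
such as `Gln/Lys` or `C3DC/C4OH`. Throughout the statistics these are
single measured variables; they are only expanded into their
identification variants for pathway analysis (below).

# Univariate screening

Groups are compared pairwise per analyte with the Mann–Whitney test:
the exact null distribution when `min(n, m) <= 8` without ties, otherwise
the tie-corrected normal approximation. The approximation is used
*without* the continuity correction: at the cohort sizes this pipeline
targets (10–27 per group) the corrected variant is conservative (empirical
type-I rate ≈ 0.040 at nominal 0.05 for 13 vs 10), while the uncorrected
variant sits at the nominal level. P-values are adjusted across the
57-analyte panel with the Benjamini–Hochberg step-up, separately within
each pairwise comparison — this matches how per-comparison significance
statements are usually made for such panels, and avoids pooling
comparisons with different power. Two flags are reported: raw `p < alpha`
(the conventional basis for "changed in at least one comparison" marker
shortlists) and the stricter FDR-surviving `q < alpha`.

Association with time post-insult is summarized by Spearman's rank
correlation of concentration against sampling hour (average ranks for
ties; two-sided t-approximation p-values, since sampling times are heavily
tied). PCA of the autoscaled significant compounds provides the standard
visual check that the 0 h and 6 h groups separate; zero-variance analytes
are dropped with a warning rather than silently imputed.

# Differential correlation networks

For two groups, per-group adjacency matrices are built as the absolute
Spearman correlation of every analyte pair (`a_ij = |rho_ij|`). No
soft-threshold power is applied: the assay reports 57 well-quantified
variables, not thousands of noisy ones, and raising `|rho|` to a power
would only compress an already small dynamic range. The rewiring of pair
`(i, j)` between groups is `c_ij = |a_ij^(1) - a_ij^(2)|`, and the default
clustering dissimilarity is `d_ij = 1 - c_ij / max(C)` with zero diagonal,
so *strongly co-rewired pairs cluster together*. The opposite reading of a
"difference matrix" (rewired pairs far apart, `d = c`) is available via
`direction = "change_as_distance"`; the default was chosen because the
scientific object of interest is groups of compounds whose mutual coupling
changes together. If `C` is identically zero the dissimilarity is
undefined and a `no_rewiring` flag is returned instead of a degenerate
clustering.

Analytes are clustered by agglomerative hierarchical clustering with Ward
linkage on the precomputed dissimilarity. We use the `ward.D2`
(Lance–Williams) convention — conventions differ between software and this
is stated explicitly because it changes merge heights. The dendrogram is
cut at every candidate `k` (default `2:min(10, n - 1)`) and the cut with
the maximum mean silhouette width, computed against the same
dissimilarity, is selected.

Rank correlations at n ≈ 11–27 per group are noisy (the sampling SD of a
single rho at n = 11 is ≈ 0.3), so planted-partition recovery is only
tested at larger simulated group sizes; on real cohorts of this size the
cluster composition should be read as exploratory.

# Pathway over-representation with ambiguous identifications

A marker list drawn from the panel may contain combined codes. One marker
name-set is created per combination of identification variants (Cartesian
product: `{Gln/Lys, C3DC/C4OH}` yields 4 sets), and each set is tested for
enrichment in every pathway compound-set by the one-sided hypergeometric
tail: `p = P(X >= hits)` with the library universe as population. A
pathway is *consensus-significant* only when `p < 0.1` in **every**
variant set; p and the enrichment ratio (observed/expected hits) are
averaged over sets, and the hit count is summarized by its median. The
0.1 level and the all-sets rule follow the screening convention that an
identification ambiguity must not manufacture enrichment: a pathway
supported by only one reading of an ambiguous code is not reported as
significant. No multiplicity correction is applied across pathways — the
procedure is a ranking/triage step, not a confirmatory family of tests.

Pathway libraries are consumed as GMT files; nothing is fetched from
SMPDB or KEGG. The shipped `example_pathways_synthetic.gmt` is a small
synthetic stand-in collection for tests and examples. By default the
universe is restricted to the panel's own compound variants (63 names for
the default panel) — the assay can only ever observe those compounds, so
using the full library space would overstate significance; the
library-wide universe remains available (`universe = "library"`).

# OPLS-DA

The discriminant core is a from-scratch orthogonal PLS for binary class
labels. X is autoscaled (unit variance; Pareto scaling available) and y
centered. Each orthogonal component is obtained by the orthogonal
signal correction step: compute the PLS weight `w ∝ X'y`, the loading `p`
of its score, remove from `p` the part collinear with `w`, normalize to
get `w_o`, and deflate X by the resulting component. After `n_ortho` such
removals a single predictive PLS component is fitted on the filtered
matrix. With `n_ortho = 0` the model *is* one-component PLS1 (verified to
1e-8 against an independent implementation in the tests).

Reported statistics: `R2X` (fraction of scaled-X sum of squares captured
by all modeled components; the X sum-of-squares decomposition is exact and
tested), `R2Y` (fraction of centered-y sum of squares described), and `Q2
= 1 - PRESS/SS` from leave-one-out cross-validation in which the left-out
sample never contributes to centering, scaling or any component. VIP
scores are computed over the predictive plus orthogonal components with
each component's squared normalized weights weighted by the y sum of
squares it explains; this keeps `mean(VIP^2) = 1` exactly, and because
orthogonal components explain essentially no y variance it reduces in
practice to the predictive-component VIP (also available explicitly via
`vip_mode = "pred"`).

Classification uses the cross-validated predicted `y-hat` scores. The
decision cutoff is chosen by maximizing Youden's J on those scores — the
selection rule is a package choice (reported cutoffs in small-cohort
studies rarely state one); since J weights sensitivity and specificity
equally, it is the neutral default for a diagnostic screen. The component
counts follow the study designs: 2 orthogonal components for the 3 h
model, 4 for the 6 h model, both exposed as parameters.

# The stepwise logistic diagnostic model

The builder mirrors a four-stage construction:

1. **Feature expansion.** From `p` base analytes: the concentrations, their
   squares, and all pairwise products — `2p + p(p-1)/2` features (1710 for
   the full panel), deterministically ordered.
2. **VIP prefilter.** An OPLS-DA model is fitted on the expanded matrix and
   features with `VIP > 1` survive. Because the VIP mean-square is pinned
   at 1, this can never pass everything; it typically halves the set.
3. **Forward AIC selection.** Starting from the intercept-only logistic
   model, the feature whose addition lowers AIC most is added until no
   addition lowers it. Fits use iteratively reweighted least squares with
   a fixed iteration cap.
4. **Backward p-elimination.** The coefficient with the largest p-value
   for zero-equality is dropped and the model refitted until all p < 0.05.

Perfect separation deserves a note: with n ≈ 22 and a strong marker, the
first selected feature often separates the classes completely. The MLE
then diverges, and the Wald statistic of the *separating* feature
collapses toward zero (the Hauck–Donner effect) — naive backward
elimination would absurdly drop the best feature. The builder therefore
flags separated fits, stabilizes them with a small ridge penalty for
reporting and prediction, and switches the elimination test to drop-one
likelihood-ratio p-values, which remain well behaved. The flag and the
test used (`p_type`) are recorded on the model.

Model quality is assessed by leave-one-out cross-validation in which the
*entire* builder — prefilter, forward selection, elimination — is re-run
inside every fold, so feature selection never sees the held-out sample
(a leakage test in the suite verifies that flipping a held-out label
cannot change the fold's model). Held-out probabilities are pooled into a
ROC curve; AUC is trapezoidal and equals the Mann–Whitney identity
`U/(n1·n0)` exactly, ties included.

One caveat on LOO with in-fold selection at these sample sizes: under the
null (no signal), folds frequently select the intercept-only model, whose
held-out "probability" is the training class rate — which is
anti-correlated with the held-out label. Null AUCs are therefore biased
*below* 0.5, not centered on it; the suite checks the informative
direction (no optimistic bias).

# Repeated split validation

`split_validation()` pools controls and 6 h HIE samples from the
time-course and hypothermia experiments (10 + 13 controls vs 12 + 14 HIE)
and repeats 100 stratified 70/30 train/test splits. Stratification is a
deliberate choice: at n ≈ 49, unstratified splits regularly produce test
sets missing a class. Per split both models are rebuilt from scratch on
the training samples; the OPLS cutoff is chosen by Youden's J on the
training split's *LOO-CV* scores (refit scores are optimistically spread
and would misplace the cutoff), the logistic cutoff on the training
probabilities. Sensitivity and specificity are measured on the test split
and averaged. A single seeded RNG stream drives the splits; identical
seeds give identical reports.

# The synthetic cohort generator

The study's measured table is not redistributed with the package, so every
stage is exercised on synthetic cohorts with the structure the analyses
assume. Concentrations are drawn log-normally:
`x = exp(log(median * fold) + sdlog * z)`, with `z` standard multivariate
normal. Log-normal marginals are the natural choice for concentrations
(positive, right-skewed), and because the downstream tests are rank-based
or autoscaled, only this monotone multiplicative structure matters.
Group effects are fold-changes on the median; correlation is induced on
the log scale in non-overlapping equicorrelated blocks (within-block
`rho`, default 0.4 within compound classes), whose positive
semi-definiteness is checked (`rho >= -1/(k-1)`).

The shipped scenarios plant the reported effect *directions* at the
study's group sizes: glycine up 1.5-fold at 3 h and 2-fold at 6 h,
methionine down (0.7) at 6 h, the listed acylcarnitine increases,
succinylacetone up, deoxyadenosine down; the inflammation scenario raises
the short-chain acylcarnitines under LPS but lowers them under LPS+HIE;
the hypothermia scenario raises ornithine, valine and Leu/Ile/Hyp and
lowers the lysophosphatidylcholines relative to normothermia. The
magnitudes are stand-ins — the study reports directions and significance,
not effect sizes — fixed once so that the univariate stage reproduces the
qualitative significance pattern (glycine the sole FDR survivor at 3 h)
at the study's n. Baseline medians are class-typical DBS values (e.g.
glycine 230 µmol/L, short acylcarnitines 0.15–1.5 µmol/L) with log-SD 0.3.
Correlation rewiring between groups is planted by giving a group its own
block specification.

What the generator does **not** emulate: assay chemistry, instrument and
batch noise, censoring at detection limits, inter-analyte correlations
beyond block structure, and any real metabolic kinetics. Passing tests on
these cohorts therefore validate the *statistical machinery* — rank tests,
FDR control, component extraction, selection logic, cross-validation
hygiene — not the biological effect sizes, which only the measured data
can supply.

# Numerical and design choices, in brief

* Two-sided tests throughout; directions are reported separately.
* BH adjustment within each pairwise comparison, not pooled.
* Ward clustering: `ward.D2` on the precomputed dissimilarity;
  silhouette computed against the same dissimilarity.
* ORA universe defaults to the panel's compound variants; `alpha = 0.1`
  per-set with the all-sets consensus rule; no cross-pathway correction.
* OPLS scaling: unit variance by default, Pareto optional; exactly one
  predictive component for binary y; `n_ortho` must stay below the rank
  of the scaled matrix.
* Youden's J selects all classification cutoffs; ties broken toward
  higher sensitivity, then the lower threshold.
* Forward-only AIC stage; separation handled by ridge stabilization plus
  likelihood-ratio elimination tests (flags recorded).
* All generators and resampling draw from a private seeded RNG stream and
  restore the global RNG state.

Test problem sizes were chosen to keep the full suite to a few minutes:
oracle enumerations at n ≤ 6 (Mann–Whitney) and universes ≤ 15 (ORA),
planted-recovery runs at 20–100 seeds with the study's group sizes, and
correlation-recovery runs at n = 200–1000 where rank correlations are
estimable.

# Known limitations

* Effect magnitudes, variances and baseline medians in the generator are
  stand-ins; headline numbers computed on synthetic cohorts are not the
  study's numbers and will differ from any measured dataset.
* The default panel fills catalogue slots that the study narrative does
  not pin down with standard screening codes flagged
  `placeholder = TRUE`; override the panel to match a real assay sheet.
* The cutoff-selection rule (Youden) is a package choice; published
  cutoffs selected by another rule will not be reproduced exactly.
* LOO-based metrics at n ≈ 22 have high variance; treat per-model
  sensitivity/specificity as estimates with wide intervals, and prefer
  the repeated split validation for comparing models.
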