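---
title: "Methods: annotation Bayes factors for GWAS variant prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotation Bayes factors for GWAS variant prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`funcprior` estimates, for every variant in a GWAS panel, the odds that it
is causal (or in high LD with a causal variant) given its functional
annotations, and combines those odds with association evidence in a
Bayesian factorization.

**Labels.** The positive class is the set of known GWAS hits: catalog SNPs
present in the panel with reported p below a tier cutoff — `weak`,
p < 1e-5, or `strong`, p < 5e-8; both cutoffs are strict, and when one SNP
has several catalog entries its minimum reported p governs the tier.
Non-hits are panel variants that are neither hits nor in LD (r² ≥ 0.8,
inclusive) with any hit; variants in between are excluded, so
hits + non-hits + LD-excluded partition the panel exactly. Sex chromosomes
and the MHC region (chr6:29,624,809–33,160,245 on build 37, atypical LD
and gene density) are removed up front.

**Annotation.** Each variant carries binary features (presence in a peak,
eQTL status, gene context, ...) and non-negative quantitative features
(conservation scores, averaged over overlapping score blocks, 0 when no
block overlaps). Internally coordinates are 1-based inclusive; BED input
(0-based half-open) is converted on read, so a SNP at `pos` overlaps a BED
record `(start, end)` iff `start < pos ≤ end`. Every variant then receives,
per feature, the **maximum** value over itself and its LD proxies
(r² ≥ 0.8): a proxy carrying an annotation carries the index variant's
association signal, so the annotation is attributed to the index variant
too. Related binary columns (one histone mark across cell types, all TFBS
experiments, all eQTL experiments) can be collapsed to "any of" indicators
("clumped" analysis) or kept separate ("separated").

**Fit.** With class counts `N_hit`, `N_nonhit`, hits are weighted by
`(N_hit + N_nonhit) / (2 N_hit)` and non-hits by
`(N_hit + N_nonhit) / (2 N_nonhit)` — each class carries exactly half the
total weight. The weighted Bernoulli likelihood is penalized by the elastic
net, `λ[α‖β‖₁ + (1−α)/2‖β‖₂²]`, the intercept left unpenalized; fitting is
delegated to glmnet (coordinate descent, convergence threshold 1e-7 by
default), with predictors standardized internally and coefficients
reported on the original scale. `(α, λ)` are chosen to minimize mean
weighted binomial deviance over stratified, seed-determined
cross-validation folds.

**Bayes factors.** Because the classes are weighted to equal mass, the
prior odds inside the fitted model are 1 and the fitted odds
`score/(1 − score)` estimate the annotation Bayes factor directly; note
`BF_annot = exp(β₀ + βᵀx)` exactly. Association evidence uses Wakefield's
approximation with a `N(0, W)` prior on the effect:
`BF_assoc = √(V/(V+W)) exp(z²W / (2(V+W)))`, the alternative-over-null
direction (the reciprocal of Wakefield's original null-over-alternative
form), so that both factors point the same way and posterior odds are
`O_prior · BF_assoc · BF_annot`. Ranking uses the product only; no default
`O_prior` is ever assumed.

## Tunable parameters

* `r2_threshold` (default **0.8**, inclusive): LD threshold for both
  proxy annotation propagation and non-hit exclusion. The proxy relation is
  treated as symmetric (r² is symmetric); missing directions are filled in.
* `prior_sd` (default **0.2**): prior SD of the association effect
  (log-odds or standardized beta), `W = prior_sd²`. `W = 0` gives
  `BF_assoc = 1` for any z. When `se` is unavailable, `z` is recovered from
  the two-sided p with the sign of the effect estimate.
* `alpha_grid` (default 0, 0.1, ..., 1) and `lambda_grid` (default:
  glmnet's log-spaced 100-point path from λ_max downward, per alpha).
* `n_folds` (default **10**); splits `simple_60_40` (60% train / 40% test)
  and `nested_70_30` (42% train / 28% tune / 30% test), both stratified by
  class and fully seed-determined.
* `min_positives` (default **11**): a PPV is only reported at a threshold
  where at least this many hits are correctly identified; fewer positives
  make the ratio too unstable to quote.

## Numerical and statistical choices

These are places where the method leaves the convention open; the package
fixes one and states it:

* **Fisher's exact test** is two-sided by the probability-mass rule (sum of
  hypergeometric probabilities ≤ that of the observed table, with a 1e-7
  relative guard against floating-point ties) — the most common convention.
  Zero-margin tables return p = 1 with a warning.
* **Odds-ratio intervals** are Woolf normal intervals on the log OR, with
  the Haldane–Anscombe +0.5 correction applied to *all* cells iff any cell
  is zero.
* **Feature correlations** are Pearson, on the 0/1 and raw score columns;
  zero-variance columns get correlation 0 and are flagged rather than NA.
* **λ selection** is the CV-deviance minimum, not the one-SE rule.
* **AUC** is the Mann–Whitney form (ties count ½), identical to the
  trapezoidal area; QQ expected quantiles use the `(i − 0.5)/n` plotting
  position; QQ score bins default to five equal-frequency (quintile) bins.
* **Ranks**: larger BF → smaller rank; ties take the average of their span.
* **Control matching**: controls must sit within 0.25 of a hit's −log10 p
  (the same half-decade); if a stratum is empty the tolerance widens by
  half-decades with a warning, then the call fails.
* The generator's intercept is solved by `uniroot` (tolerance 1e-10) so the
  mean hit probability equals the target fraction.
* The full-data refit used for Bayes factors recomputes the class weights
  on the full data (the natural reading; the alternative — freezing the
  training-set weights — changes only the intercept scale).

## The synthetic world

`sim_config()` states a desk-scale world shaped like the real clumped
analysis, and its defaults are fixed once:

* 14 features with the published non-hit carrier frequencies of the clumped
  annotation set (from ~7e-5 for miRNA targets to ~0.57 for H3K4Me1);
  PhyloP/PhastCons-like features are quantitative (positive part of the
  latent Gaussian), the rest binary.
* Correlated binaries come from thresholding a block-structured latent
  Gaussian (`L_j = √ρ·U_block + √(1−ρ)·ε_j`), i.e. a tetrachoric model:
  conservation pair ρ = 0.8, regulatory block (three histone marks + TFBS)
  ρ = 0.6 — the two strong correlation structures seen in real clumped
  annotation data. Note the *binary* correlation is attenuated relative to
  ρ (for ρ = 0.99 at frequency 0.5 the phi correlation is ≈ 0.91).
* True coefficients: nonsynonymous-like 1.0, several mid-size effects
  0.2–0.4, rare features (splice, miRNA, TSS) exactly 0; intercept solved
  for a 5% hit fraction.
* Summary statistics: non-hits null (`z ~ N(0,1)`), hits with true effects
  `N(0, 0.05²)` at `se = 1/√n_eff = 0.01` — genome-wide-significant
  territory for a typical hit.
* LD proxies: Poisson(2) proxies per variant, r² uniform on [0.8, 1],
  emitted as *satellite* ids (off-panel reference-panel variants). This
  mirrors proxies drawn from a sequencing panel rather than the array, and
  it is what makes annotation propagation idempotent: a second pass sees
  the satellites as absent (all-zero) rows and changes nothing. With
  index–index LD edges a second pass would take a two-step maximum; the
  package does not re-propagate already-propagated matrices.

What the generator deliberately does **not** emulate: genomic coordinates
(positions are placeholders, so no positional LD structure), annotation
frequency differences between causal and merely-tagging variants, effect
sizes correlated with allele frequency, and the long-tailed score
distributions of real conservation tracks. A green recovery test therefore
establishes that the estimator recovers a known logistic world of realistic
sparsity and correlation — not that real ENCODE-era tracks would reproduce
any published coefficient table.

## What the tests establish

The acceptance suite is property-based: exact algebraic identities
(weights, odds transform, log-additivity, tie-averaged ranks, strict
thresholds); equivalence against independent oracles (exhaustive
hypergeometric enumeration for every 2×2 table with margins ≤ 30, the
two-normal density ratio for Wakefield BFs to 1e-12, pairwise Mann–Whitney
counting for the AUC on all labelings with n ≤ 8, a hand-written
Newton–Raphson weighted MLE for the λ→0 limit of the elastic net);
seeded recovery at n = 30,000 (held-out AUC within ±0.05 of the generative
Bayes-optimal AUC, sign recovery of all |β| ≥ 0.3 coefficients, null-model
AUC in [0.45, 0.55]); integration checks (positive rank-sum improvement
for true hits in ≥90% of replicates versus ≤50% for p-value-matched
control sets; top-quintile QQ dominance under informative annotations and
none under the association null); and byte-identical reruns of the seeded
command-line pipeline.

## Known limitations

* `BF_annot` inherits the assumptions of the factorization: enrichment
  patterns are taken as identical across allele frequencies and effect
  sizes, and "causal" really means "causal or in high LD with a causal
  variant".
* Elastic-net coefficients carry no confidence intervals; for standard
  errors refit unpenalized (λ = 0 is supported) and use classical logistic
  asymptotics.
* Scores of exactly 0 or 1 (possible only with separable data at λ = 0)
  have no finite odds and are rejected rather than clamped.
* Computing r² from genotype panels, genome-build liftover, and native
  UCSC/ENCODE binary formats are out of scope; LD is consumed precomputed
  (PLINK/VCFtools-style tables).
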