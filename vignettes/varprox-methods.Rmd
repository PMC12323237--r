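---
title: "Methods: proxy-label deleteriousness models from standing variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proxy-label deleteriousness models from standing variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varprox)
```

## The model

`varprox` approximates variant pathogenicity by deleteriousness under
purifying selection: alleles that damage fitness are held at low
population frequency, so frequency strata of standing variation can
serve as surrogate labels. Frequent variants (MAF ≥ 0.001) act as
proxy-benign (label 0); rare variants (MAF < 0.001, AC > 1) or
singletons (AC = 1) act as proxy-deleterious (label 1). Variants with
AF > 0.5 are excluded before stratification — above that point the
*alternate* allele is the major allele and the frequency argument
inverts. The surrogate labels are heavily noisy by construction (most
rare variants are neutral); the modelling bet, which the package's
synthetic experiments reproduce, is that a simple, strongly regularized
learner extracts the shared signal despite the mislabeling.

The learner is an L2-regularized logistic regression on standardized
annotation-derived features, minimizing

$$\sum_i w_i\,\bigl[\log(1+e^{z_i}) - y_i z_i\bigr]
  \;+\; \frac{1}{2C}\lVert\beta\rVert^2,
  \qquad z_i = x_i^\top\beta + b,$$

with \(C = 1\) and the intercept unpenalized. Because the features are
z-normalized, the fitted coefficients are directly comparable and serve
as feature importances. The raw score \(\sigma(z)\) is read as the
probability of a deleterious effect; for reporting it is PHRED-scaled
by rank among a reference score set, \(-10\log_{10}(r/N)\), so PHRED 20
marks the top 1% of the reference.

### Iteration snapshots

Rather than training to convergence, the optimizer state is recorded
after every L-BFGS iteration \(k = 1..K\) from a common zero
initialization (implemented as refits with an increasing iteration cap,
which keeps each snapshot exactly the state after \(k\) iterations of a
single run). Early iterations act as implicit regularization on the
noisy surrogate labels; the deployed snapshot is chosen by the
unweighted mean of \((\mathrm{AUROC}+\mathrm{AUPRC})/2\) across
external validation sets — unweighted because validation sets differ
wildly in size; the 50/50 combination rule is our choice where only
"both metrics, averaged" is conventionally fixed, and it is exposed in
code rather than hard-wired into a constant. Ties resolve to the
smallest iteration; with no validation data the conventional iteration
13 is used. Standing-variation pairs default to \(K = 20\); the large
combined-cohort pairs (`hs`, `hfs` and their `-all` variants) to
\(K = 50\).

## Label leakage and matching

Two nuisance channels separate the frequency strata without any
biology:

1. **Substitution spectrum.** Strata differ in their ref→alt
   composition (C→T: 40.1% of frequent variants versus 29.8% of
   singletons). A model given only substitution-class indicators can
   exploit this. `matched_sample()` therefore draws the
   proxy-deleterious subsample so its 12-class SNV spectrum (and InDel
   length distribution, capped at 50 bp — the benchmark length limit
   makes longer classes irrelevant) matches the benign set, using
   largest-remainder apportionment with ties broken by canonical class
   order for exact reproducibility. Matching uses the 12 directional
   classes without strand collapsing or CpG context: the observed skew
   is reported directionally, and context is the simulator's concern,
   not the matcher's.
2. **Variant density.** Annotations describing local variant abundance
   are correlated with the frequency-derived labels themselves. Every
   pair is therefore trainable with and without the `variant_density`
   feature group (apostrophe-suffixed identifiers keep it), and group
   exclusion propagates through feature crosses.

Unbalanced pairs (`hs-all`, `hfs-all`) skip matching to retain the full
singleton set and instead weight classes so the summed weight per label
is equal — minority weight \(n_{maj}/n_{min}\), majority 1. This is the
simplest rule consistent with "increase the class weights of the
minority cohort", and integer weights are exactly equivalent to row
duplication (a property the tests assert).

SNVs and InDels are balanced as separate universes throughout, since
stratum counts and subsample sizes are bookkept per variant type.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `maf_frequent` | 0.001 | MAF bound (inclusive) for the frequent stratum |
| `singleton_ac` | 1 | allele count defining a singleton |
| `af_exclude_above` | 0.5 | drop variants whose AF exceeds this |
| `l2_C` | 1 | inverse L2 strength |
| `max_iterations` | 20 (50 combined) | snapshot count |
| `default_iteration` | 13 | fallback snapshot |
| InDel length cap | 50 bp | spectrum class pooling bound |
| ClinVar length cap | 50 bp | benchmark allele-length bound (inclusive) |

MPRA thresholds are taken as written in the source assays: regulatory =
activity `A_logP, B_logP > 3`, `Skew_logP > 4`, `|skewStat| ≥ 1` in ≥ 3
of 5 cell types; neutral = activity `> 4`, `Skew_logP < 2`,
`|skewStat| ≤ 0.15` in ≥ 4 of 5 cell types, excluding splice and
(non-)coding exonic consequences — read literally as the coding
partition plus `SPLICE_SITE`, `CANONICAL_SPLICE` and
`NONCODING_CHANGE`. Variants qualifying for both labels (possible only
through duplicate measurements across experiments) are removed from
both sets.

## The synthetic-data generator

The generator exists so that every stage — stratification, matching,
featurization, training, selection, scaling, evaluation — runs and is
tested without any download. It emulates:

- **Site frequency spectrum**: allele counts follow \(P(AC=i) \propto
  i^{-\alpha}\) truncated at AF 0.5, with \(\alpha = 1\) (the neutral
  1/i law) and a cohort of 142,312 haplotypes. Latent-deleterious sites
  use exponent \(\alpha \cdot \texttt{rare\_shift}\) with
  `rare_shift = 2`, concentrating them at low counts.
- **Latent state**: `deleterious_fraction = 0.6` of sites carry the
  hidden deleterious state. This is far above any genome-wide estimate
  of the selected fraction; it is a deliberate compression. The
  generator drops the vast neutral majority of a real genome so that,
  at \(10^4\)–\(10^5\) sites, every stratum still contains enough of
  both states for training and for feasible spectrum matching. With
  these settings the stratum ordering matches real population data
  (singletons ≈ 40%, rare ≈ 39%, frequent ≈ 21% of sites) and the rare
  stratum is roughly 60% latent-deleterious.
- **Substitution spectra**: class-conditional on the realized frequency
  class. The C→T proportions (0.401 frequent, 0.298 singleton) are the
  empirically motivated anchors; the remaining entries are stylized —
  chosen once, analytically, so that (a) a class-indicator-only
  classifier reaches AUROC ≈ 0.65 on an unmatched pair and ≈ 0.5 on a
  matched one, and (b) matched sampling is per-class feasible with
  ≥ 10% margin at the default strata. The rare-class spectrum is the
  midpoint of the other two.
- **Annotations**: six signal columns `effect × state + N(0, 1)` with
  effects (1.5, 1.2, 1.0, 0.8, 0.6, 0.4) — distinct values so that
  coefficient recovery is a meaningful correlation — six pure-noise
  decoys, two categorical columns with state-dependent level
  frequencies, 5% missing cells, and one `variant_density`-tagged
  column whose mean shifts by `density_leak_strength = 2` for
  low-frequency variants, reproducing the density-leakage phenomenon:
  it tops the coefficient list of density-inclusive models and is
  absent from density-excluded ones.
- **Validation labels**: balanced draws from the two latent states with
  a 5% chance of replacing each label by a coin flip, emulating noisy
  clinical assertions; the latent truth travels in a sidecar table that
  no pipeline stage reads.

What the generator does **not** emulate: linkage, demography,
mutation-rate maps, CpG context, InDels (spectrum matching of InDel
lengths is exercised through hand-built records in the tests), realistic
annotation correlation structure, and the extreme class imbalance of a
real genome. Passing tests therefore demonstrate the machinery —
stratification, leakage control, optimization, selection, scaling — not
real-data performance; headline benchmark numbers on ClinVar-scale data
are out of reach at desk scale by design.

## Numerical conventions and degenerate inputs

- AUROC is the Mann–Whitney pairwise probability with ties counted
  half, computed from average ranks; AUPRC is step-wise average
  precision with ties broken by stable input order (conservative
  relative to trapezoidal PR interpolation). Single-class inputs raise
  errors rather than returning a default.
- Spearman's rho is the Pearson correlation of average ranks with the
  large-sample t approximation for its two-sided p-value.
- Normalization uses the population (divide-by-n) standard deviation;
  constant columns map to all-zero rather than dividing by zero, and
  scoring-time matrices always reuse frozen training statistics.
- PHRED ranks are averaged over ties and clamped to \([1, N]\): scores
  above every reference value take the top rank, scores below every
  reference value map to PHRED 0.
- Categorical levels are fixed at training time; unseen scoring-time
  levels map to all-zero indicators with a warning (the non-crashing
  choice).
- Multi-allelic VCF sites are decomposed into one record per alternate
  allele, conserving the per-site alternate allele count — population
  resources do not fix a convention here, so decomposition is flagged
  as ours.
- The AF > 0.5 exclusion is applied before the singleton/rare/frequent
  split, and when matching is enabled it is applied to every
  proxy-deleterious source; both orderings are defensible and ours is
  recorded here.
- The singleton definition is AC = 1 everywhere, including the binned
  allele-frequency analysis (a frequency of exactly 1 would describe a
  fixed allele, contradicting the singleton concept).

## Problem sizes

The test suite and the acceptance script run the full pipeline on
simulations of 5·10^3–10^5 sites (training pairs of up to ~4·10^4
records, ~20 features), chosen as the smallest sizes at which stratum
proportions, matching feasibility and metric estimates are stable to
well within the asserted tolerances. At these sizes the complete suite
and the acceptance script each finish in well under a minute on a
single CPU.

## Known limitations

- The generator's `deleterious_fraction` and spectra are calibrated for
  desk-scale testability, not biological realism (see above).
- `v1-6`-style pairs require both cohorts as inputs; the germline
  de-novo variant simulator of the original framework is not
  re-implemented.
- Population-stratified allele frequencies, liftOver/strand
  harmonization, and annotation computation are out of scope; inputs
  are assumed harmonized to one assembly with precomputed annotations.
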