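---
title: "Fusing heterogeneous assay tables for delivery-system screening: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing heterogeneous assay tables for delivery-system screening: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoptml)
options(nanoptml.quiet = TRUE)
```

## The modelling problem

Two evidence streams describe a candidate nanoparticle–drug delivery
system. Drug assays report an activity value under one of several endpoint
conventions (IC50 in nM, Ki in nM, % inhibition, ...), each with its own
scale and its own notion of "good". Nanoparticle assays report
cytotoxicity or ecotoxicity values, again endpoint-specific, under
conditions (cell line, shape, coat, exposure time) that strongly shape the
measurement. No single regression target spans this heterogeneity. The
package's approach makes three moves:

1. **Desirability binarization.** Every observed value $v$ is reduced to
   $f_{obs} \in \{0, 1\}$ by an endpoint-specific cutoff and a
   desirability sign $d$: $f_{obs} = 1$ iff $v > \text{cutoff}$ when
   $d = +1$, or $v < \text{cutoff}$ when $d = -1$. Inequalities are
   strict, so a value sitting exactly on the cutoff is classed
   undesirable for either sign — ties carry no evidence of desirability,
   and the conservative reading keeps the positive class clean.
2. **Perturbation features.** Descriptors enter the model only as
   deviations from label-conditioned moving averages,
   $\Delta D = D - \langle D \rangle_c$: the model sees how a case
   departs from the average case measured under the same condition label,
   which is what makes assays from incompatible endpoint conventions
   commensurable.
3. **Pair fusion.** A (drug assay, NP assay) pair becomes one case with
   both sides' deviation features, a joint reference prior, and the label
   $y = f_{obs}^{drug} \wedge f_{obs}^{NP}$: the system is worth pursuing
   only if the drug is active *and* the carrier tolerable.

The assumptions this encodes: endpoint cutoffs are meaningful per endpoint
(they are configuration, not estimation); condition labels partition
assays into groups whose descriptor means are stable enough to serve as
references; and drug activity and carrier safety interact only through the
conjunction, not through a pair-specific mechanism — pairing is a
combinatorial resampling of independent evidence, which is precisely what
lets a few hundred NP assays be stretched across thousands of drug assays.

## Parameters that matter

- **Cutoffs and desirability** (`discretization_spec`): same units as each
  endpoint's $v$. The shipped defaults (e.g. IC50 cutoff 1000 nM with
  $d = -1$; NP CC50 cutoff 40 µg/ml with $d = +1$) are demonstration
  values for the synthetic data; on real data they are scientific choices
  the analyst must own, supplied as YAML.
- **Conditioning labels** (`pt_feature_spec`): each deviation feature is
  conditioned on a *single* label field, by default the activity-parameter
  label of its own table (`c_d0` / `c_n0`). Conditioning on one field
  keeps groups populated — conditioning on the full label vector would
  shatter the tables into singleton groups whose deviations are
  identically zero. The mapping is configuration because richer label-set
  conditioning is a legitimate alternative when data are dense.
- **Joint reference prior** (`joint_reference`): the product of the two
  marginal group frequencies, i.e. an independence assumption, matching
  the conjunctive label; `min` and `mean` are provided for sensitivity
  analysis. Observed tree splits on the joint prior in fitted models sit
  in the 0.05–0.12 range, consistent with small products of marginals.
- **Fusion** (`fuse`): target 500,000 pairs drawn uniformly without
  replacement; 75/25 stratified split; seed 42 everywhere a seed is
  needed. Moving averages and priors are fitted on the assay rows
  referenced by training pairs only (`fit_on = "train"`): a validation
  case may share an assay row with training cases, but no statistic is
  ever computed *from* rows only validation cases reference. The
  `fit_on = "all"` flag reproduces whole-dataset fitting for comparison.
- **Decision tree** (`train_classifier(algo = "dt")`): gini criterion, no
  cost-complexity pruning (`cp = 0`), depth cap 15, minimum 5 cases per
  leaf and 2 per split, class weights 0.4/0.6 (down-weighting the majority
  negative class), best-split search over all features. In `rpart`,
  `minsplit = 2` with `minbucket = 5` reproduces the leaf/split constraint
  pair exactly; `rpart`'s exhaustive splitter is deterministic, so the
  reference configuration's random-state parameter has no analogue here.
  Other algorithms run at library defaults, overridable per call — their
  role is comparison, not tuning.
- **Reporting** (`evaluate`): confusion matrices at the 0.5 probability
  threshold; Sn/Sp printed to 1 decimal, MCC to 4 — full precision is
  retained in the returned objects. AUROC uses the rank (Mann–Whitney)
  form of the trapezoidal rule; average ranks on tied scores equal the
  trapezoid drawn through tie-induced ROC segments.
- **Grid simulation** (`build_prediction_set`, `heatmap_aggregate`):
  heatmap bins green/yellow/red at 2/3 and 1/3 of predicted probability —
  even thirds, configurable, since no canonical cut points exist. Cells
  whose (cell line, coat) combination appears fewer than `min_support = 1`
  times in the original assay data are masked: a mean over pure
  extrapolation should not be colour-coded as evidence. Rows order by
  coat McGowan volume ascending, ties alphabetical.

## What the synthetic generator emulates

`gen_drug_assays()` / `gen_np_assays()` reproduce the *statistical shape*
the pipeline assumes: 4403 drug assays over 2566 drugs and 260 NP assays
over 31 particles by default (totals allocated exactly — one assay
minimum per entity, remainder multinomial — so the corpus ratios 1.72 and
8.39 assays/entity are reproduced exactly at the default sizes); uniform
label catalogues; normal LOGP and exposure time, lognormal PSA, NP length,
core volume and coat volumes (sign-constrained quantities); coat volumes
shared by all assays of a coat label.

Positives are planted through a logistic model on standardized descriptor
deviations, and the observed value $v$ is then placed on the corresponding
side of its endpoint's cutoff, strictly — the generator cannot bypass the
discretization contract, because positivity is *defined* through the same
`observed_function` the pipeline applies. The logistic intercept is solved
numerically (by `uniroot`) so the marginal positive rate equals the
configured baseline whether or not a signal is planted; baselines of 0.30
(drug) and 0.23 (NP) were chosen once so the fused conjunction prevalence
lands near 7%, the regime the method is meant for (rare positives, strong
class imbalance).

What it does **not** emulate: real chemistry. Descriptors are draws from
marginal distributions, not properties of molecules; labels are
uncorrelated with descriptors; repeated assays of an entity differ only
through assay-level noise; and the planted signal is additive on a logit
scale. Passing tests therefore demonstrate that the machinery — fusion,
leakage-safe statistics, learning, reporting — recovers structure that is
present by construction. They say nothing about whether six deviation
features suffice for any particular real corpus.

## Numerical and degenerate-case choices

- Ties at the cutoff → 0, for either desirability sign (strictness above).
- Group means use exact group frequencies; `p \cdot n` is asserted to be
  the integer positive count. Unseen label levels at apply time fall back
  to the global mean (deviations) or global positive rate (priors), with
  a logged count — prediction grids deliberately contain combinations the
  training data never saw.
- Centering identity: fitted-and-applied on the same rows, within-group
  deviation means vanish to 1e−9 absolute; this is the invariant the test
  suite checks rather than any particular mean value.
- Stratified splitting uses largest-remainder rounding so the training
  partition is exactly `round(train_frac * N)` while class quotas differ
  from exact proportionality by less than one case; a class with fewer
  than two cases aborts rather than silently producing a single-class
  partition.
- Single-class partitions make AUROC (and possibly Sn or Sp) undefined:
  reports carry `NA` with a warning instead of failing, so a sweep over
  many models survives a degenerate partition.
- Confusion-cell arithmetic is done in double precision (the four-marginal
  MCC product overflows 32-bit integers at corpus scale) with the MCC
  denominator computed in log space.

## Problem sizes

The test suite runs on tables of 100–1500 assays and fused sets of
1200–6000 cases (about six seconds end to end), with one full-scale check
— 500,000 fused cases from the default corpus sizes — exercising the
exact split arithmetic. The acceptance script runs the full 500,000-case
pipeline including decision-tree training (under ten seconds). These sizes
are the package's chosen demonstration scale; all of them are
configuration, and the same code paths run unchanged at larger targets.

## Known limitations

- Pair resampling treats repeated assays of the same (drug, NP) entity
  pair as distinct cases; no deduplication or importance weighting is
  offered.
- The conjunction label ignores any genuine drug–carrier interaction
  (e.g. coat-dependent release kinetics); such effects can only enter
  through the descriptors.
- kNN prediction scales poorly beyond ~10^5 training cases; it is included
  for comparison at moderate sizes, not for corpus-scale screening.
- The heatmap's support masking keys on (cell line, coat) only; a cell can
  be unmasked yet rest on thin evidence along unmasked dimensions — the
  per-cell `support` column is reported so users can apply stricter
  masking.
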