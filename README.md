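# nanoptml

Information-fusion + perturbation-theory machine learning for screening
nanoparticle–drug delivery systems.

Preclinical evidence about candidate delivery systems for neurodegenerative
disease drugs is scattered across two very different kinds of tables: drug
bioactivity assays (thousands of compounds, heterogeneous endpoints such as
IC50, Ki or % inhibition, measured against many targets, cell lines and
organisms) and nanoparticle cytotoxicity/ecotoxicity assays (few particles,
many conditions: cell line or organism, shape, coating agent, exposure
time). No single table supports a model of the *combined* question: will
this drug, on this carrier, be both active and safe? `nanoptml` is for
computational chemists and nanomedicine groups who want to fuse those two
evidence streams into one labelled case table, train and audit classifiers
on it, and scan large combinatorial grids of candidate systems before
committing to synthesis.

## The method

Each assay's observed value *v* is binarized by a per-endpoint cutoff and a
desirability sign *d* (*d* = +1 to maximize, −1 to minimize):

    f(v)_obs = 1  iff  (v > cutoff and d = +1) or (v < cutoff and d = −1)

Descriptors are turned into perturbation-theory deviation features against
label-conditioned moving averages — for descriptor *D* and conditioning
label *c*:

    ΔD = D − ⟨D⟩_c

i.e. how far this case sits from the average of all assays run under the
same condition label. The default feature set is the drug polar surface
area deviation plus five nanoparticle deviations (safety time, NP length,
core volume, coat McGowan volume, coat van der Waals volume). Each side
also contributes a reference prior — the group frequency
p(f_obs = 1 | label) — and the pair-level prior is the product of the two
marginals by default.

Drug and NP assays are then fused by uniform pair resampling: each sampled
(drug assay, NP assay) pair becomes one case with the six ΔD features, the
joint prior, and the class label y = f_obs(drug) AND f_obs(NP) — an
attractive delivery system needs an active drug *and* a tolerable carrier.
Cases are split 75/25 (stratified) and classifiers — decision tree (the
reference configuration), LDA, kNN, random forest, gradient boosting — are
fitted on the training partition, with moving averages and priors fitted on
training-referenced assay rows only. Reports give the confusion matrix,
sensitivity, specificity, MCC and trapezoidal AUROC; fitted trees can be
summarized as depth-truncated "families", and fitted models drive
combinatorial prediction grids (cores × cell lines × shapes × coats ×
drugs) aggregated into masked three-bin probability heatmaps.

## Worked example

Everything below runs from the built-in synthetic generator — no downloads.

```r
library(nanoptml)

cfg  <- synth_config(seed = 42, n_drugs = 1170, n_drug_assays = 2000,
                     n_nps = 24, n_np_assays = 200)
drug <- apply_discretization(gen_drug_assays(cfg), default_discretization("drug"))
np   <- apply_discretization(gen_np_assays(cfg),   default_discretization("np"))
summarize_table(np)
#> np assay table: 200 assays, 24 entities, 8.33 assays/entity

pairs <- sample_pairs(nrow(drug), nrow(np), 20000, seed = 42)
fused <- fuse(drug, np, pairs, default_pt_features(), seed = 42)
fused
#> <fused_dataset> 20000 cases (15000 train / 5000 valid), 6.69% class 1
#> features: delta_psa, delta_t, delta_lnp, delta_vnpu, delta_vxcoat, delta_vvdwmgcoat

dt <- train_classifier(fused, "dt")
evaluate(dt, fused, "v")
#> DT [v] n=5000  Sp 95.3  Sn 56.4  MCC 0.4710  AUROC 0.9168
#>       predicted
#> actual    0   1
#>      0 4444  221
#>      1  146  189
```

The validation report reads: of 5000 held-out fused cases, 95.3% of the
undesirable systems are rejected (specificity) and 56.4% of the desirable
ones recovered (sensitivity); the AUROC of 0.92 shows the planted
descriptor signal is learned well beyond chance. Truncating the tree two
layers down explains what drives it:

```r
dt_families(dt, depth = 2)
#>   node depth                                          path n_cases n_pred1  frac_pred1
#> 1    4     2 delta_vxcoat< 110.8 & delta_vvdwmgcoat< 34.87    9858      86 0.005733333
#> 2    5     2 delta_vxcoat< 110.8 & delta_vvdwmgcoat>=34.87    1769     146 0.009733333
#> 3    6     2        delta_vxcoat>=110.8 & delta_psa>=2.713    1273      59 0.003933333
#> 4    7     2        delta_vxcoat>=110.8 & delta_psa< 2.713    2100     840 0.056000000
```

Family 4 — large positive coat-volume deviation combined with
below-average drug polar surface area — concentrates most of the predicted
positives (5.6% of all training cases), which is how the family tables are
meant to be read when short-listing systems for assay. A fitted model can
then score a grid (`levels_from_tables()`, `build_prediction_set()`,
`heatmap_aggregate()`) or the whole workflow can be run from one
configuration with `run_pipeline()`; `inst/cli/nanoptml.R` wraps the same
functions for shell use.

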