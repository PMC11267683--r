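options(nanoptml.quiet = TRUE)

# Small, fast synthetic tables shared across test files; every table is
# regenerated from a fixed seed so the suite carries no stored fixtures.
small_cfg <- function(seed = 7) {
  synth_config(seed = seed, n_drugs = 150, n_drug_assays = 260,
               n_nps = 12, n_np_assays = 100)
}

small_tables <- function(seed = 7) {
  cfg <- small_cfg(seed)
  list(
    cfg = cfg,
    drug = apply_discretization(gen_drug_assays(cfg), default_discretization("drug")),
    np = apply_discretization(gen_np_assays(cfg), default_discretization("np"))
  )
}

small_fused <- function(seed = 7, n_pairs = 4000, ...) {
  tabs <- small_tables(seed)
  pairs <- sample_pairs(nrow(tabs$drug), nrow(tabs$np), n_pairs, seed = seed)
  fuse(tabs$drug, tabs$np, pairs, default_pt_features(), seed = seed, ...)
}

# Minimal hand-built drug table: n rows spread over ids, constant labels.
flat_drug_table <- function(n, ids, v = 1, psa = 50, logp = 2) {
  df <- data.frame(
    drug_id = rep_len(ids, n), v = v,
    c_d0 = "IC50 (nM)", c_d1 = "TP01", c_d2 = "CL01", c_d3 = "Homo sapiens",
    c_d4 = "SINGLE PROTEIN", c_d5 = "B", c_d6 = "Expert", c_d7 = "CS9",
    c_d8 = "Direct", logp = logp, psa = psa,
    stringsAsFactors = FALSE
  )
  assay_table(df, "drug")
}
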