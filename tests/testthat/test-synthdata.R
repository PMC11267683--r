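test_that("generation is deterministic per seed and passes validation untouched", {
  cfg <- small_cfg(2)
  d1 <- gen_drug_assays(cfg)
  d2 <- gen_drug_assays(cfg)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  n1 <- gen_np_assays(cfg)
  n2 <- gen_np_assays(cfg)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  expect_false(identical(as.data.frame(d1),
                         as.data.frame(gen_drug_assays(small_cfg(3)))))

  expect_equal(attr(d1, "n_dropped"), 0)
  expect_equal(attr(n1, "n_dropped"), 0)
})

test_that("assay totals and per-entity means follow the configuration", {
  d <- gen_drug_assays(small_cfg(4))
  expect_equal(nrow(d), 260)                       # exact total allocation
  expect_equal(length(unique(d$drug_id)), 150)

  # Poisson mode: mean assays/drug close to the configured mean at scale
  cfg <- synth_config(seed = 6, n_drugs = 2566, n_drug_assays = NULL,
                      assays_per_drug_mean = 1.72)
  s <- summarize_table(gen_drug_assays(cfg))
  expect_lt(abs(s$n_rows / s$n_entities - 1.72), 0.1)

  cfg_np <- synth_config(seed = 6, n_nps = 31, n_np_assays = NULL,
                         assays_per_np_mean = 8.39,
                         n_drugs = 10, n_drug_assays = NULL)
  s_np <- summarize_table(gen_np_assays(cfg_np))
  expect_lt(abs(s_np$n_rows - 260), 3 * sqrt(31 * 7.39))  # expectation check
})

test_that("positive rates match the configured baselines", {
  # zero planted signal: plain Bernoulli at the baseline rate
  cfg0 <- synth_config(seed = 8, n_drugs = 600, n_drug_assays = 1500,
                       n_nps = 40, n_np_assays = 800,
                       signal = c(delta_psa = 0, delta_t = 0, delta_lnp = 0,
                                  delta_vnpu = 0, delta_vxcoat = 0,
                                  delta_vvdwmgcoat = 0))
  d0 <- apply_discretization(gen_drug_assays(cfg0), default_discretization("drug"))
  se <- sqrt(0.3 * 0.7 / nrow(d0))
  expect_lt(abs(mean(d0$f_obs) - 0.30), 3 * se)

  # planted signal: the intercept calibration keeps the marginal rate
  cfg1 <- synth_config(seed = 8, n_drugs = 600, n_drug_assays = 1500,
                       n_nps = 40, n_np_assays = 800)
  n1 <- apply_discretization(gen_np_assays(cfg1), default_discretization("np"))
  se_np <- sqrt(0.23 * 0.77 / nrow(n1))
  expect_lt(abs(mean(n1$f_obs) - 0.23), 4 * se_np)
})

test_that("coat volumes are shared within a coat label", {
  np <- gen_np_assays(small_cfg(10))
  per_coat <- tapply(np$vxcoat, np$c_n4, function(x) length(unique(x)))
  expect_true(all(per_coat == 1))

  # conditioning the deviation on the coat label therefore zeroes it out
  spec <- pt_feature_spec(data.frame(name = "delta_vxcoat", flavour = "np",
                                     descriptor = "vxcoat", label_field = "c_n4"))
  feats <- delta_features(np, fit_moving_averages(np, spec), spec)
  expect_true(all(abs(feats[, 1]) < 1e-9))
})

test_that("the end-to-end fixture drives the full pipeline", {
  dir <- withr::local_tempdir()
  fx <- gen_end_to_end_fixture(small_cfg(12), dir = dir)
  expect_true(all(file.exists(unlist(fx$paths))))
  drug <- apply_discretization(read_assay_table(fx$paths$drug, "drug"),
                               read_discretization_spec(fx$paths$disc_drug))
  np <- apply_discretization(read_assay_table(fx$paths$np, "np"),
                             read_discretization_spec(fx$paths$disc_np))
  pairs <- sample_pairs(nrow(drug), nrow(np), 3000, seed = 12)
  fused <- fuse(drug, np, pairs, read_pt_feature_spec(fx$paths$features),
                seed = 12)
  expect_setequal(unique(fused$y), c(0, 1))
  m <- train_classifier(fused, "dt")
  ev <- evaluate(m, fused, "v")
  expect_true(is.finite(ev$auroc))
})
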