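toy_levels <- function(n_cores = 2, n_cells = 3, n_shapes = 2, n_coats = 4,
                       n_drugs = 3) {
  grid_levels(
    cores = data.frame(core = paste0("core", seq_len(n_cores)),
                       lnp = seq_len(n_cores) * 10,
                       vnpu = seq_len(n_cores) * 1000),
    cell_lines = data.frame(cell_line = paste0("cell", seq_len(n_cells)),
                            assay_class = "cytotoxicity"),
    shapes = paste0("shape", seq_len(n_shapes)),
    coats = data.frame(coat = paste0("coat", seq_len(n_coats)),
                       vxcoat = rev(seq_len(n_coats)) * 100,
                       vvdwmgcoat = rev(seq_len(n_coats)) * 80),
    drugs = data.frame(drug_id = paste0("drug", seq_len(n_drugs)),
                       logp = 2, psa = 50 + seq_len(n_drugs),
                       c_d0 = "IC50 (nM)")
  )
}

test_that("grid_size is the exact product of the catalogue sizes", {
  expect_equal(grid_size(toy_levels(1, 1, 1, 1, 1)), 1)
  expect_equal(grid_size(toy_levels(2, 3, 1, 1, 1)), 6)
  lv <- toy_levels(2, 3, 2, 4, 3)
  expect_equal(grid_size(lv),
               nrow(expand.grid(1:2, 1:3, 1:2, 1:4, 1:3)))  # enumeration oracle
  expect_error(grid_levels(lv$cores[0, ], lv$cell_lines, lv$shapes, lv$coats,
                           lv$drugs), "non-empty")
})

test_that("prediction sets enumerate exactly, deterministically, and bounded", {
  fused <- small_fused(seed = 11, n_pairs = 2000)
  stats <- attr(fused, "stats")
  lv <- toy_levels()
  n <- grid_size(lv)
  full <- build_prediction_set(lv, n, seed = 1, stats = stats)
  expect_equal(nrow(full), n)
  combos <- unique(full[, c("core", "cell_line", "shape", "coat", "drug_id")])
  expect_equal(nrow(combos), n)  # every combination exactly once

  s1 <- build_prediction_set(lv, 20, seed = 9, stats = stats)
  s2 <- build_prediction_set(lv, 20, seed = 9, stats = stats)
  expect_identical(s1, s2)
  expect_error(build_prediction_set(lv, n + 1, seed = 1, stats = stats),
               "exceeds grid size")

  # materialized features follow the fitted statistics
  expect_true(all(is.finite(as.matrix(full[, stats$spec$name]))))
  expect_true(all(full$joint_ref >= 0 & full$joint_ref <= 1))
})

test_that("heatmap cells are brute-force group means with masking and order", {
  lv <- toy_levels()
  fused <- small_fused(seed = 11, n_pairs = 2000)
  pred <- build_prediction_set(lv, grid_size(lv), seed = 2,
                               stats = attr(fused, "stats"))
  set.seed(12)
  pred$p <- runif(nrow(pred))
  hm <- heatmap_aggregate(pred, lv)

  key <- paste(pred$coat, pred$core, pred$cell_line, pred$shape)
  hm_key <- paste(hm$coat, hm$core, hm$cell_line, hm$shape)
  oracle <- tapply(pred$p, key, mean)
  expect_equal(hm$mean_p, as.numeric(oracle[hm_key]))
  oracle_n <- tapply(pred$p, key, length)
  expect_equal(hm$support, as.integer(oracle_n[hm_key]))

  # permutation invariance in prediction row order
  hm_perm <- heatmap_aggregate(pred[sample(nrow(pred)), ], lv)
  expect_equal(hm_perm, hm)

  # rows ordered by coat McGowan volume ascending (coat4 has the smallest)
  expect_equal(unique(hm$coat), paste0("coat", 4:1))

  # bin assignment is monotone in the cell mean
  expect_true(all(hm$mean_p[hm$bin == "green"] >= 2 / 3))
  expect_true(all(hm$mean_p[hm$bin == "yellow"] >= 1 / 3 &
                  hm$mean_p[hm$bin == "yellow"] < 2 / 3))
  expect_true(all(hm$mean_p[hm$bin == "red"] < 1 / 3))

  pred$p <- 1
  expect_true(all(heatmap_aggregate(pred, lv)$bin == "green"))
})

test_that("cells unsupported by the reference assays are masked", {
  lv <- toy_levels()
  fused <- small_fused(seed = 11, n_pairs = 2000)
  pred <- build_prediction_set(lv, grid_size(lv), seed = 3,
                               stats = attr(fused, "stats"))
  pred$p <- 1  # would be green everywhere without masking
  # reference data supporting only (cell1, coat1)
  np <- small_tables(11)$np
  ref <- np[rep(1, 4), , drop = FALSE]
  ref$c_n1 <- "cell1"
  ref$c_n4 <- "coat1"
  ref <- assay_table(as.data.frame(ref), "np")
  hm <- heatmap_aggregate(pred, lv, min_support = 1, support_reference = ref)
  supported <- hm$cell_line == "cell1" & hm$coat == "coat1"
  expect_true(all(hm$bin[supported] == "green"))
  expect_true(all(hm$bin[!supported] == "masked"))
})

test_that("application presets vary exactly one catalogue", {
  lv <- toy_levels(2, 3, 2, 4, 3)
  expect_equal(grid_size(application_preset("coat_scan", lv)), 4)
  expect_equal(grid_size(application_preset("drug_scan", lv)), 3)

  manual <- grid_levels(lv$cores,
                        lv$cell_lines[lv$cell_lines$cell_line == "cell1", ],
                        lv$shapes,
                        lv$coats[lv$coats$coat == "coat1", ],
                        lv$drugs[lv$drugs$drug_id == "drug1", ],
                        defaults = lv$defaults, np_defaults = lv$np_defaults)
  core_scan <- application_preset("core_scan", lv)
  expect_equal(core_scan$cores, manual$cores)
  expect_equal(core_scan$shapes, manual$shapes)
  expect_equal(core_scan$coats, manual$coats)
  expect_equal(core_scan$drugs, manual$drugs)
  expect_error(application_preset("core_scan", lv, varied = lv$cores[0, ]),
               "non-empty")
})
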