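test_that("pair sampling is exhaustive, duplicate-free and seed-reproducible", {
  all4 <- sample_pairs(2, 2, 4)
  expect_equal(nrow(all4), 4)
  expect_equal(nrow(unique(all4)), 4)

  p1 <- sample_pairs(300, 40, 2000, seed = 5)
  p2 <- sample_pairs(300, 40, 2000, seed = 5)
  p3 <- sample_pairs(300, 40, 2000, seed = 6)
  expect_identical(p1, p2)
  expect_false(identical(p1, p3))
  expect_equal(anyDuplicated(p1), 0)
  expect_true(all(p1$drug_idx >= 1 & p1$drug_idx <= 300))
  expect_true(all(p1$np_idx >= 1 & p1$np_idx <= 40))

  expect_error(sample_pairs(3, 3, 10), "9")

  # full enumeration of the corpus-sized pair space
  expect_equal(nrow(sample_pairs(4403, 260, 4403 * 260)), 1144780)
})

test_that("fusion labels follow the combiner and a counting oracle", {
  tabs <- small_tables(17)
  pairs <- sample_pairs(nrow(tabs$drug), nrow(tabs$np), 4000, seed = 17)
  fused <- fuse(tabs$drug, tabs$np, pairs, default_pt_features(), seed = 17)

  f_d <- tabs$drug$f_obs[pairs$drug_idx]
  f_n <- tabs$np$f_obs[pairs$np_idx]
  expect_identical(fused$y, as.integer(f_d & f_n))
  expect_equal(sum(fused$y), sum(f_d == 1 & f_n == 1))
  expect_identical(fused$f_obs_drug, f_d)
  expect_identical(fused$f_obs_np, f_n)
  expect_true(all(fused$joint_ref >= 0 & fused$joint_ref <= 1))

  drug_only <- fuse(tabs$drug, tabs$np, pairs, default_pt_features(),
                    combiner = "drug_only", seed = 17)
  expect_identical(drug_only$y, f_d)

  bad <- pairs
  bad$np_idx[1] <- nrow(tabs$np) + 1
  expect_error(fuse(tabs$drug, tabs$np, bad, default_pt_features()), "dangling")
})

test_that("fused labels are content-keyed under input row permutation", {
  tabs <- small_tables(23)
  pairs <- sample_pairs(nrow(tabs$drug), nrow(tabs$np), 1500, seed = 23)
  fused <- fuse(tabs$drug, tabs$np, pairs, default_pt_features(), seed = 23)

  perm <- withr::with_seed(1, sample.int(nrow(tabs$drug)))
  drug_perm <- tabs$drug[perm, , drop = FALSE]
  remap <- match(seq_len(nrow(tabs$drug)), perm)
  pairs_perm <- data.frame(drug_idx = remap[pairs$drug_idx], np_idx = pairs$np_idx)
  fused_perm <- fuse(drug_perm, tabs$np, pairs_perm, default_pt_features(),
                     seed = 23)
  expect_identical(fused_perm$y, fused$y)
  expect_identical(fused_perm$drug_id, fused$drug_id)
})

test_that("the stratified split hits its sizes and preserves prevalence", {
  fused <- small_fused(seed = 29, n_pairs = 6000)
  expect_equal(sum(fused$partition == "t"), round(0.75 * 6000))

  resplit <- split_train_valid(fused, train_frac = 0.6, seed = 2)
  expect_equal(sum(resplit$partition == "t"), round(0.6 * 6000))

  prev_t <- mean(fused$y[fused$partition == "t"])
  prev_v <- mean(fused$y[fused$partition == "v"])
  expect_lt(abs(prev_t - prev_v), 0.005)  # within 0.5 percentage points

  # the tiny balanced case: 3 train / 1 valid with both classes in train
  mini <- fused[c(which(fused$y == 1)[1:2], which(fused$y == 0)[1:2]), ]
  mini_split <- split_train_valid(mini, 0.75, seed = 1)
  expect_equal(sum(mini_split$partition == "t"), 3)
  expect_setequal(unique(mini_split$y[mini_split$partition == "t"]), c(0, 1))

  lone <- fused[c(which(fused$y == 1)[1], which(fused$y == 0)[1:5]), ]
  expect_error(split_train_valid(lone), "2 cases per class")
})

test_that("fused prevalence tracks the product of the marginal rates", {
  tabs <- small_tables(41)
  pairs <- sample_pairs(nrow(tabs$drug), nrow(tabs$np), 8000, seed = 41)
  fused <- fuse(tabs$drug, tabs$np, pairs, default_pt_features(), seed = 41)
  expected <- mean(tabs$drug$f_obs) * mean(tabs$np$f_obs)
  se <- sqrt(expected * (1 - expected) / nrow(fused))
  expect_lt(abs(mean(fused$y) - expected), 5 * se + 0.01)
})
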