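# Hand-built fused dataset for controlled model tests.
toy_fused <- function(x, y, partition = rep("t", length(y))) {
  df <- data.frame(drug_assay = seq_along(y), np_assay = seq_along(y),
                   drug_id = "d", np_id = "n",
                   delta_psa = x, delta_t = 0, delta_lnp = 0, delta_vnpu = 0,
                   delta_vxcoat = 0, delta_vvdwmgcoat = 0,
                   joint_ref = 0.5, f_obs_drug = y, f_obs_np = y,
                   y = y, partition = partition, stringsAsFactors = FALSE)
  structure(df, class = c("fused_dataset", "data.frame"),
            feature_names = c("delta_psa", "delta_t", "delta_lnp", "delta_vnpu",
                              "delta_vxcoat", "delta_vvdwmgcoat"))
}

test_that("confusion-matrix metrics agree with a per-case tally oracle", {
  set.seed(3)
  for (i in 1:5) {
    y <- rbinom(400, 1, 0.3)
    pred <- rbinom(400, 1, 0.4)
    cm <- confusion_matrix(tn = sum(y == 0 & pred == 0), fp = sum(y == 0 & pred == 1),
                           fn = sum(y == 1 & pred == 0), tp = sum(y == 1 & pred == 1))
    m <- metrics_from_cm(cm)
    expect_equal(m$sn, 100 * mean(pred[y == 1] == 1))
    expect_equal(m$sp, 100 * mean(pred[y == 0] == 0))
    # MCC equals the Pearson correlation of the two binary vectors
    expect_equal(m$mcc, cor(y, pred), tolerance = 1e-12)
    # invariance under a simultaneous class swap
    swapped <- confusion_matrix(tn = cm$tp, fp = cm$fn, fn = cm$fp, tp = cm$tn)
    expect_equal(metrics_from_cm(swapped)$mcc, m$mcc)
  }
  # symmetric no-association table
  expect_equal(metrics_from_cm(confusion_matrix(50, 30, 30, 50))$mcc, 0.25)
  expect_equal(metrics_from_cm(confusion_matrix(40, 40, 40, 40))$mcc, 0)
  expect_error(metrics_from_cm(confusion_matrix(10, 5, 0, 0)), "Sn")
  expect_error(metrics_from_cm(confusion_matrix(0, 0, 5, 10)), "Sp")
})

test_that("trapezoidal AUROC is calibrated and matches an external ROC", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c(0, 1), c(0.5, 0.5)), 0.5)
  expect_error(auroc(c(1, 1), c(0.2, 0.3)), "single class")

  set.seed(8)
  y <- rbinom(10000, 1, 0.3)
  p <- runif(10000)
  perms <- replicate(20, auroc(sample(y), p))
  expect_lt(abs(mean(perms) - 0.5), 0.03)

  skip_if_not_installed("pROC")
  for (i in 1:3) {
    y <- rbinom(500, 1, 0.4)
    p <- round(runif(500), 2)  # force ties
    expect_equal(auroc(y, p),
                 as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
                 tolerance = 1e-12)
  }
})

test_that("the decision tree separates separable data and is deterministic", {
  set.seed(4)
  x <- c(rnorm(100, -3), rnorm(100, 3))
  ds <- toy_fused(x, rep(c(0L, 1L), each = 100))
  m <- train_classifier(ds, "dt")
  ev <- evaluate(m, ds, "t")
  expect_equal(ev$sn, 100)
  expect_equal(ev$sp, 100)
  expect_equal(ev$auroc, 1)

  fused <- small_fused(seed = 19)
  m1 <- train_classifier(fused, "dt")
  m2 <- train_classifier(fused, "dt")
  expect_identical(predict_proba(m1, fused), predict_proba(m2, fused))
  expect_error(train_classifier(toy_fused(x, rep(1L, 200)), "dt"), "single class")
})

test_that("every algorithm trains and returns probabilities", {
  fused <- small_fused(seed = 37, n_pairs = 1200)
  for (algo in c("dt", "lda", "knn", "rf", "gb")) {
    m <- train_classifier(fused, algo,
                          hyper = list(ntree = 50, nrounds = 20, k = 7))
    p <- predict_proba(m, fused[fused$partition == "v", ])
    expect_true(all(p >= 0 & p <= 1), info = algo)
    ev <- evaluate(m, fused, "v")
    expect_equal(ev$cm$tn + ev$cm$fp + ev$cm$fn + ev$cm$tp, ev$n, info = algo)
  }
})

test_that("evaluate reports defined metrics when AUROC is undefined", {
  set.seed(6)
  x <- c(rnorm(50, -3), rnorm(50, 3))
  ds <- toy_fused(x, rep(c(0L, 1L), each = 50),
                  partition = c(rep("t", 80), rep("v", 20)))
  m <- train_classifier(ds, "dt")
  w <- testthat::capture_warnings(ev <- evaluate(m, ds, "v"))
  expect_true(any(grepl("undefined", w)))
  expect_true(is.na(ev$auroc))
  expect_equal(ev$sn, 100)  # validation rows are all actual positives here
})

# Independent router: rebuilds each split (variable, threshold, direction)
# from the fitted tree's split table and walks cases down to `depth`.
rpart_truncated_route <- function(fit, x, depth) {
  frame <- fit$frame
  nodes <- as.integer(rownames(frame))
  info <- list()
  idx <- 1
  for (r in seq_len(nrow(frame))) {
    if (as.character(frame$var[r]) != "<leaf>") {
      info[[as.character(nodes[r])]] <- list(
        var = as.character(frame$var[r]),
        thresh = fit$splits[idx, "index"],
        ncat = fit$splits[idx, "ncat"]
      )
      idx <- idx + frame$ncompete[r] + frame$nsurrogate[r] + 1
    }
  }
  vapply(seq_len(nrow(x)), function(i) {
    node <- 1
    while (floor(log2(node)) < depth && !is.null(info[[as.character(node)]])) {
      s <- info[[as.character(node)]]
      left <- if (s$ncat < 0) x[i, s$var] < s$thresh else x[i, s$var] >= s$thresh
      node <- if (left) 2 * node else 2 * node + 1
    }
    node
  }, numeric(1))
}

test_that("tree families partition the training set and match a routing oracle", {
  fused <- small_fused(seed = 43, n_pairs = 3000)
  m <- train_classifier(fused, "dt")

  fam1 <- dt_families(m, depth = 1)
  expect_equal(nrow(fam1), 2)
  n_train <- sum(fused$partition == "t")
  for (d in 0:3) {
    fam <- dt_families(m, depth = d)
    expect_equal(sum(fam$n_cases), n_train)
    expect_equal(sum(fam$frac_pred1), sum(fam$n_pred1) / n_train)
  }

  train_x <- as.data.frame(fused)[fused$partition == "t",
                                  c(attr(fused, "feature_names"), "joint_ref")]
  oracle_nodes <- rpart_truncated_route(m$fit, train_x, depth = 2)
  fam2 <- dt_families(m, depth = 2)
  oracle_counts <- table(oracle_nodes)
  expect_equal(fam2$n_cases,
               as.numeric(oracle_counts[as.character(fam2$node)]))

  # a stump on separable data yields all-or-nothing class-1 families
  set.seed(5)
  sep <- toy_fused(c(rnorm(100, -4), rnorm(100, 4)), rep(c(0L, 1L), each = 100))
  stump <- train_classifier(sep, "dt", hyper = list(maxdepth = 1))
  fam_s <- dt_families(stump, depth = 1)
  expect_setequal(fam_s$n_pred1 / fam_s$n_cases, c(0, 1))

  expect_warning(dt_families(stump, depth = 5), "clipped")
  expect_error(dt_families(train_classifier(small_fused(47, 1000), "lda")),
               "decision tree")
})
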