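#' Confusion matrix
#'
#' Actual class by predicted class counts for a binary classifier.
#'
#' @param tn,fp,fn,tp Non-negative integer counts (true negative, false
#'   positive, false negative, true positive).
#' @return A list of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fp, fn, tp) {
  cells <- c(tn = tn, fp = fp, fn = fn, tp = tp)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop_contract("confusion-matrix cells must be non-negative integers")
  }
  structure(as.list(cells), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(actual = c("0", "1"), predicted = c("0", "1")))
  print(m)
  invisible(x)
}

#' Sensitivity, specificity and MCC from a confusion matrix
#'
#' `Sn = 100 * tp / (tp + fn)`, `Sp = 100 * tn / (tn + fp)`, and the Matthews
#' correlation coefficient
#' `MCC = (tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`.
#' Values are returned at full precision; reports round Sn/Sp to 1 decimal
#' and MCC to 4 decimals.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with `sn` (%), `sp` (%), `mcc`.
#' @export
metrics_from_cm <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tn <- as.numeric(cm$tn); fp <- as.numeric(cm$fp)
  fn <- as.numeric(cm$fn); tp <- as.numeric(cm$tp)
  if (tp + fn == 0) stop_contract("Sn undefined: no actual positives")
  if (tn + fp == 0) stop_contract("Sp undefined: no actual negatives")
  sn <- 100 * tp / (tp + fn)
  sp <- 100 * tn / (tn + fp)
  marg <- c(tp + fp, tp + fn, tn + fp, tn + fn)
  mcc <- if (any(marg == 0)) {
    stop_contract("MCC undefined: a confusion-matrix marginal is zero")
  } else {
    (tp * tn - fp * fn) / exp(0.5 * sum(log(marg)))
  }
  list(sn = sn, sp = sp, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Threshold-free AUROC from predicted class-1 probabilities by the
#' trapezoidal rule, computed in its rank (Mann-Whitney) form; tied scores
#' receive average ranks, which matches the trapezoid through tie-induced
#' ROC segments.
#'
#' @param labels 0/1 vector of actual classes.
#' @param probs Numeric vector of predicted class-1 probabilities or scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, probs) {
  stopifnot(length(labels) == length(probs), all(labels %in% c(0, 1)))
  n1 <- as.numeric(sum(labels == 1))
  n0 <- as.numeric(sum(labels == 0))
  if (n1 == 0 || n0 == 0) {
    stop_contract("AUROC undefined: partition contains a single class")
  }
  r <- rank(probs, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

model_features <- function(ds) c(attr(ds, "feature_names"), "joint_ref")

dt_default_hyper <- function() {
  list(cp = 0, maxdepth = 15, minbucket = 5, minsplit = 2,
       class_weight = c(`0` = 0.4, `1` = 0.6), split = "gini")
}

#' Train a classifier on a fused dataset
#'
#' Fits one of five algorithms on the training partition only, using the
#' deviation features plus the joint reference prior as inputs. The decision
#' tree defaults mirror the reference configuration: gini criterion, no
#' cost-complexity pruning (`cp = 0`), maximum depth 15, minimum 5 cases per
#' leaf and 2 per split, class weights 0.4 (class 0) / 0.6 (class 1), best
#' splitter, unrestricted features and leaf count. Other algorithms use
#' library defaults, overridable through `hyper`.
#'
#' @param ds A `fused_dataset` with a training partition containing both
#'   classes.
#' @param algo One of `"dt"`, `"lda"`, `"knn"`, `"rf"`, `"gb"`.
#' @param hyper Named list of hyperparameter overrides. For `dt`:
#'   `cp`, `maxdepth`, `minbucket`, `minsplit`, `class_weight`; `knn`: `k`
#'   (default 5); `rf`: `ntree` (default 500), `seed`; `gb`: `nrounds`
#'   (default 100), `max_depth`, `eta`, `seed`.
#' @return A fitted model handle of class `ptml_model`.
#' @export
train_classifier <- function(ds, algo = c("dt", "lda", "knn", "rf", "gb"),
                             hyper = list()) {
  algo <- match.arg(algo)
  stopifnot(inherits(ds, "fused_dataset"))
  feats <- model_features(ds)
  train <- ds$partition == "t"
  x <- as.matrix(as.data.frame(ds)[train, feats, drop = FALSE])
  y <- ds$y[train]
  if (length(unique(y)) < 2) stop_contract("training partition holds a single class")

  fit <- switch(algo,
    dt = {
      h <- utils::modifyList(dt_default_hyper(), hyper)
      w <- ifelse(y == 1, h$class_weight[["1"]], h$class_weight[["0"]])
      dat <- data.frame(x, y = factor(y, levels = c(0, 1)))
      rpart::rpart(y ~ ., data = dat, weights = w, method = "class",
                   parms = list(split = h$split),
                   control = rpart::rpart.control(
                     cp = h$cp, maxdepth = h$maxdepth, minbucket = h$minbucket,
                     minsplit = h$minsplit, xval = 0))
    },
    lda = MASS::lda(x, grouping = factor(y, levels = c(0, 1))),
    knn = list(x = x, y = y, k = hyper$k %||% 5),
    rf = {
      ntree <- hyper$ntree %||% 500
      with_seed(hyper$seed %||% 42,
        randomForest::randomForest(x, factor(y, levels = c(0, 1)), ntree = ntree))
    },
    gb = {
      params <- list(objective = "binary:logistic",
                     max_depth = hyper$max_depth %||% 6,
                     eta = hyper$eta %||% 0.3,
                     nthread = 1)
      with_seed(hyper$seed %||% 42,
        xgboost::xgb.train(params = params,
                           data = xgboost::xgb.DMatrix(x, label = y),
                           nrounds = hyper$nrounds %||% 100))
    }
  )
  model <- structure(list(algo = algo, fit = fit, features = feats,
                          hyper = hyper, n_train = length(y)),
                     class = "ptml_model")
  if (algo == "dt") {
    # cache training-set routing and full-tree predictions for family reports
    model$train_pred1 <- as.integer(predict_proba(model, ds[train, , drop = FALSE]) >= 0.5)
    model$train_where <- fit$where
  }
  model
}

#' Predicted class-1 probabilities
#'
#' @param model A [train_classifier()] handle.
#' @param newdata A `fused_dataset` or data frame carrying the model's
#'   feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_proba <- function(model, newdata) {
  stopifnot(inherits(model, "ptml_model"))
  x <- as.matrix(as.data.frame(newdata)[, model$features, drop = FALSE])
  switch(model$algo,
    dt = as.numeric(predict(model$fit, data.frame(x), type = "prob")[, "1"]),
    lda = as.numeric(predict(model$fit, x)$posterior[, "1"]),
    knn = {
      pred <- class::knn(model$fit$x, x, factor(model$fit$y, levels = c(0, 1)),
                         k = model$fit$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    rf = as.numeric(predict(model$fit, x, type = "prob")[, "1"]),
    gb = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x)))
  )
}

#' @export
print.ptml_model <- function(x, ...) {
  cat(sprintf("<ptml_model> %s, %d training cases, features: %s\n",
              toupper(x$algo), x$n_train, paste(x$features, collapse = ", ")))
  invisible(x)
}

#' Evaluate a model on one partition
#'
#' Confusion matrix at the 0.5 probability threshold, sensitivity,
#' specificity, MCC, and trapezoidal AUROC. If the partition holds a single
#' class the AUROC is undefined: it is reported as `NA` with a warning while
#' the other metrics that remain defined are still returned.
#'
#' @param model A [train_classifier()] handle.
#' @param ds A `fused_dataset`.
#' @param partition `"t"` (training) or `"v"` (validation).
#' @return A list of class `metrics_report`: `model`, `partition`, `cm`,
#'   `sn`, `sp`, `mcc`, `auroc`, `n`.
#' @export
evaluate <- function(model, ds, partition = c("v", "t")) {
  partition <- match.arg(partition)
  rows <- ds$partition == partition
  if (!any(rows)) stop_contract("partition '", partition, "' is empty")
  sub <- ds[rows, , drop = FALSE]
  p <- predict_proba(model, sub)
  pred <- as.integer(p >= 0.5)
  cm <- confusion_matrix(
    tn = sum(sub$y == 0 & pred == 0),
    fp = sum(sub$y == 0 & pred == 1),
    fn = sum(sub$y == 1 & pred == 0),
    tp = sum(sub$y == 1 & pred == 1)
  )
  # undefined metrics (single-class partition, empty marginal) degrade to NA
  # with a warning instead of aborting the report
  metrics <- tryCatch(metrics_from_cm(cm), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    tp <- as.numeric(cm$tp); fn <- as.numeric(cm$fn)
    tn <- as.numeric(cm$tn); fp <- as.numeric(cm$fp)
    list(sn = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         sp = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
         mcc = NA_real_)
  })
  auc <- tryCatch(auroc(sub$y, p), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NA_real_
  })
  structure(list(model = model$algo, partition = partition, cm = cm,
                 sn = metrics$sn, sp = metrics$sp, mcc = metrics$mcc,
                 auroc = auc, n = nrow(sub)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("%s [%s] n=%d  Sp %.1f  Sn %.1f  MCC %.4f  AUROC %s\n",
              toupper(x$model), x$partition, x$n, x$sp, x$sn, x$mcc,
              ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc))))
  print(x$cm)
  invisible(x)
}

#' Metrics reports as a Table-style data frame
#'
#' One row per report: model, partition, MCC (4 dp), Sp and Sn (1 dp), and
#' the four confusion cells.
#'
#' @param reports A list of [evaluate()] results.
#' @return A data frame.
#' @export
metrics_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(model = r$model, partition = r$partition,
               mcc = round(r$mcc, 4), sp = round(r$sp, 1), sn = round(r$sn, 1),
               auroc = round(r$auroc, 4),
               tn = r$cm$tn, fp = r$cm$fp, fn = r$cm$fn, tp = r$cm$tp,
               stringsAsFactors = FALSE)
  }))
}

rpart_node_depth <- function(node) floor(log2(node))

rpart_ancestor_at <- function(node, depth) {
  d <- rpart_node_depth(node)
  while (d > depth) {
    node <- node %/% 2
    d <- d - 1
  }
  node
}

#' Decision-tree family summary at a depth truncation
#'
#' Truncates a fitted decision tree at `depth` and enumerates the resulting
#' regions ("families"): the split path from the root, the number of
#' training cases routed into the region, and the count and fraction of the
#' *whole training partition* that the full (untruncated) tree predicts as
#' class 1 within the region. Families are disjoint and cover every training
#' case.
#'
#' @param model A fitted `"dt"` [train_classifier()] handle.
#' @param depth Truncation depth (root = depth 0); clipped to the tree's
#'   depth with a warning if deeper.
#' @return A data frame of class `dt_family_table`: `node`, `depth`, `path`,
#'   `n_cases`, `n_pred1`, `frac_pred1`.
#' @export
dt_families <- function(model, depth = 2) {
  stopifnot(inherits(model, "ptml_model"))
  if (model$algo != "dt") stop_contract("dt_families needs a fitted decision tree")
  fit <- model$fit
  nodes <- as.integer(rownames(fit$frame))
  max_depth <- max(rpart_node_depth(nodes))
  if (depth > max_depth) {
    warning("truncation depth ", depth, " exceeds tree depth ", max_depth,
            "; clipped", call. = FALSE)
    depth <- max_depth
  }
  case_leaf <- nodes[fit$where]
  region <- vapply(case_leaf, rpart_ancestor_at, numeric(1), depth = depth)
  region_nodes <- sort(unique(region))
  paths <- rpart::path.rpart(fit, nodes = region_nodes, print.it = FALSE)
  n_train <- length(region)
  out <- data.frame(
    node = region_nodes,
    depth = rpart_node_depth(region_nodes),
    path = vapply(as.character(region_nodes), function(nd) {
      paste(setdiff(paths[[nd]], "root"), collapse = " & ")
    }, character(1)),
    n_cases = vapply(region_nodes, function(nd) sum(region == nd), numeric(1)),
    n_pred1 = vapply(region_nodes, function(nd) {
      sum(model$train_pred1[region == nd])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  out$frac_pred1 <- out$n_pred1 / n_train
  rownames(out) <- NULL
  structure(out, class = c("dt_family_table", "data.frame"), n_train = n_train)
}
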