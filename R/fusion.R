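#' Sample drug-NP assay pairs
#'
#' Uniform sampling without replacement over the Cartesian product of drug
#' and NP assay indices. When `target_n` equals the product, the full grid is
#' returned in deterministic (drug-major) order.
#'
#' @param n_drug_assays,n_np_assays Table sizes.
#' @param target_n Number of pairs to draw.
#' @param seed Integer seed; identical seeds give identical pair sets.
#' @return Data frame with integer columns `drug_idx`, `np_idx`; no duplicate
#'   pair appears.
#' @export
sample_pairs <- function(n_drug_assays, n_np_assays, target_n, seed = 42) {
  stopifnot(is_scalar_number(n_drug_assays), is_scalar_number(n_np_assays),
            is_scalar_number(target_n), n_drug_assays >= 1, n_np_assays >= 1)
  n_total <- as.numeric(n_drug_assays) * as.numeric(n_np_assays)
  if (target_n > n_total) {
    stop_contract("target_n (", target_n, ") exceeds the number of available pairs (",
                  format(n_total, big.mark = ","), ")")
  }
  if (n_total > .Machine$integer.max) stop_contract("pair space too large to index")
  if (target_n == n_total) {
    k <- seq_len(n_total)
  } else {
    k <- with_seed(seed, sample.int(as.integer(n_total), size = as.integer(target_n)))
  }
  data.frame(
    drug_idx = as.integer((k - 1L) %/% as.integer(n_np_assays)) + 1L,
    np_idx = as.integer((k - 1L) %% as.integer(n_np_assays)) + 1L
  )
}

# Stratified train/valid assignment. The overall training size is exactly
# round(train_frac * N); per-class quotas use largest-remainder rounding so
# prevalence is preserved as closely as integer counts allow.
split_indices <- function(y, train_frac, seed, stratify = TRUE) {
  n <- length(y)
  n_train <- round(train_frac * n)
  if (!stratify) {
    train <- rep(FALSE, n)
    train[with_seed(seed, sample.int(n, n_train))] <- TRUE
    return(train)
  }
  classes <- sort(unique(y))
  sizes <- vapply(classes, function(cl) sum(y == cl), numeric(1))
  if (any(sizes < 2)) {
    stop_contract("stratified split needs >= 2 cases per class; class(es) ",
                  paste(classes[sizes < 2], collapse = ", "), " too small")
  }
  quota <- train_frac * sizes
  base <- floor(quota)
  rem <- n_train - sum(base)
  if (rem > 0) {
    order_rem <- order(quota - base, decreasing = TRUE)
    base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
  } else if (rem < 0) {
    order_rem <- order(quota - base, decreasing = FALSE)
    take <- order_rem[base[order_rem] > 0][seq_len(-rem)]
    base[take] <- base[take] - 1
  }
  train <- rep(FALSE, n)
  with_seed(seed, {
    for (i in seq_along(classes)) {
      idx <- which(y == classes[i])
      train[idx[sample.int(length(idx), base[i])]] <- TRUE
    }
  })
  train
}

#' Fuse drug and NP assay tables into a labelled case table
#'
#' Builds one fused case per sampled pair: the perturbation-theory deviation
#' features of both sides, the joint reference prior, the two observed
#' functions, and the binary class label. The default combiner is `and`: a
#' delivery-system case is positive only when the drug assay meets its
#' desirability criterion *and* the NP assay meets its own (an active drug on
#' a safe carrier). Moving averages and reference priors are fitted on the
#' assay rows referenced by training-partition pairs only (`fit_on =
#' "train"`, the default), so validation cases never contribute to the
#' statistics that shape their own features; `fit_on = "all"` reproduces
#' whole-dataset fitting for comparison.
#'
#' @param drug_table,np_table [assay_table()]s carrying `f_obs`
#'   (see [apply_discretization()]).
#' @param pairs Data frame from [sample_pairs()] (or any `drug_idx`/`np_idx`
#'   index pairs into the two tables).
#' @param spec A [pt_feature_spec()].
#' @param combiner `"and"` (default), `"drug_only"` or `"np_only"`.
#' @param joint_mode Combination rule for the marginal priors, see
#'   [joint_reference()].
#' @param prior_labels Named character vector: the grouping label used for the
#'   drug and NP reference priors.
#' @param train_frac,seed,stratify Partition parameters (75/25 by default);
#'   see [split_train_valid()].
#' @param fit_on `"train"` (leakage-safe default) or `"all"`.
#' @return A data frame of class `fused_dataset`: `drug_assay`, `np_assay`,
#'   ids, the feature columns in spec order, `joint_ref`, `f_obs_drug`,
#'   `f_obs_np`, `y`, `partition` (`"t"`/`"v"`). The fitted statistics are
#'   attached as `attr(x, "stats")`.
#' @export
fuse <- function(drug_table, np_table, pairs, spec,
                 combiner = c("and", "drug_only", "np_only"),
                 joint_mode = "product",
                 prior_labels = c(drug = "c_d0", np = "c_n0"),
                 train_frac = 0.75, seed = 42, stratify = TRUE,
                 fit_on = c("train", "all")) {
  combiner <- match.arg(combiner)
  fit_on <- match.arg(fit_on)
  stopifnot(inherits(drug_table, "assay_table"), inherits(np_table, "assay_table"),
            flavour(drug_table) == "drug", flavour(np_table) == "np",
            inherits(spec, "pt_feature_spec"))
  if (is.null(drug_table$f_obs) || is.null(np_table$f_obs)) {
    stop_contract("both tables need f_obs; run apply_discretization first")
  }
  if (anyDuplicated(pairs[, c("drug_idx", "np_idx")])) {
    stop_contract("duplicate (drug, np) pair")
  }
  if (any(pairs$drug_idx < 1 | pairs$drug_idx > nrow(drug_table)) ||
      any(pairs$np_idx < 1 | pairs$np_idx > nrow(np_table))) {
    stop_contract("dangling pair index")
  }

  f_d <- drug_table$f_obs[pairs$drug_idx]
  f_n <- np_table$f_obs[pairs$np_idx]
  y <- switch(combiner,
    and = as.integer(f_d == 1L & f_n == 1L),
    drug_only = f_d,
    np_only = f_n
  )
  train <- split_indices(y, train_frac, seed, stratify)

  if (fit_on == "train") {
    drug_fit <- drug_table[sort(unique(pairs$drug_idx[train])), , drop = FALSE]
    np_fit <- np_table[sort(unique(pairs$np_idx[train])), , drop = FALSE]
  } else {
    drug_fit <- drug_table
    np_fit <- np_table
  }
  ma_drug <- fit_moving_averages(drug_fit, spec)
  ma_np <- fit_moving_averages(np_fit, spec)
  priors_drug <- fit_priors(drug_fit, prior_labels[["drug"]])
  priors_np <- fit_priors(np_fit, prior_labels[["np"]])

  feat_drug <- delta_features(drug_table, ma_drug, spec)
  feat_np <- delta_features(np_table, ma_np, spec)
  p_d <- lookup_prior(priors_drug, drug_table[[prior_labels[["drug"]]]])
  p_n <- lookup_prior(priors_np, np_table[[prior_labels[["np"]]]])

  features <- cbind(feat_drug[pairs$drug_idx, , drop = FALSE],
                    feat_np[pairs$np_idx, , drop = FALSE])
  features <- features[, spec$name, drop = FALSE]  # spec order

  out <- data.frame(
    drug_assay = pairs$drug_idx,
    np_assay = pairs$np_idx,
    drug_id = drug_table$drug_id[pairs$drug_idx],
    np_id = np_table$np_id[pairs$np_idx],
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(features))
  out$joint_ref <- joint_reference(p_d[pairs$drug_idx], p_n[pairs$np_idx],
                                   mode = joint_mode)
  out$f_obs_drug <- f_d
  out$f_obs_np <- f_n
  out$y <- y
  out$partition <- ifelse(train, "t", "v")
  rownames(out) <- NULL

  structure(out,
    class = c("fused_dataset", "data.frame"),
    feature_names = spec$name,
    combiner = combiner,
    joint_mode = joint_mode,
    seed = seed,
    target_n = nrow(out),
    stats = list(ma_drug = ma_drug, ma_np = ma_np,
                 priors_drug = priors_drug, priors_np = priors_np,
                 spec = spec, prior_labels = prior_labels,
                 joint_mode = joint_mode, fit_on = fit_on)
  )
}

#' Re-partition a fused dataset into training and validation
#'
#' Stratified by class label; the training partition holds exactly
#' `round(train_frac * N)` cases and class prevalence is preserved to within
#' integer rounding. Note the feature statistics attached by [fuse()] belong
#' to the partition assigned there; re-partitioning is intended for
#' resampling experiments on fixed features.
#'
#' @param ds A `fused_dataset`.
#' @param train_frac Training fraction in (0, 1); default 0.75.
#' @param seed Integer seed.
#' @param stratify Stratify on `y` (default `TRUE`).
#' @return `ds` with the `partition` column reassigned (`"t"` / `"v"`).
#' @export
split_train_valid <- function(ds, train_frac = 0.75, seed = 42, stratify = TRUE) {
  stopifnot(inherits(ds, "fused_dataset"), nrow(ds) > 0,
            train_frac > 0, train_frac < 1)
  train <- split_indices(ds$y, train_frac, seed, stratify)
  ds$partition <- ifelse(train, "t", "v")
  ds
}

#' @export
print.fused_dataset <- function(x, ...) {
  cat(sprintf("<fused_dataset> %d cases (%d train / %d valid), %.2f%% class 1\n",
              nrow(x), sum(x$partition == "t"), sum(x$partition == "v"),
              100 * mean(x$y)))
  cat("features:", paste(attr(x, "feature_names"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.fused_dataset` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("feature_names", "combiner", "joint_mode", "seed", "target_n", "stats")) {
      attr(out, a) <- attr(x, a)
    }
    class(out) <- c("fused_dataset", "data.frame")
  }
  out
}

#' Write / read a fused dataset as CSV
#'
#' Fixed column order (ids, features in spec order, `joint_ref`, observed
#' functions, `y`, `partition`); byte-stable for identical inputs and seeds.
#'
#' @param ds A `fused_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fused_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "fused_dataset"))
  cols <- c("drug_assay", "np_assay", "drug_id", "np_id",
            attr(ds, "feature_names"),
            "joint_ref", "f_obs_drug", "f_obs_np", "y", "partition")
  utils::write.csv(as.data.frame(ds)[, cols, drop = FALSE], path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
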