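#' Discretization specification
#'
#' Maps each activity-parameter level (the `c_d0` / `c_n0` label) to a cutoff
#' on the observed value and a desirability sign: `+1` when larger values are
#' desirable (maximize), `-1` when smaller values are desirable (minimize).
#'
#' @param df Data frame with columns `c0` (character), `cutoff` (numeric) and
#'   `desirability` (integer, exactly +1 or -1).
#' @return `df` with class `discretization_spec`.
#' @export
discretization_spec <- function(df) {
  stopifnot(is.data.frame(df), all(c("c0", "cutoff", "desirability") %in% names(df)))
  df$c0 <- as.character(df$c0)
  df$cutoff <- as.numeric(df$cutoff)
  df$desirability <- as.integer(df$desirability)
  if (anyDuplicated(df$c0)) stop_contract("duplicate c0 level in discretization spec")
  if (!all(df$desirability %in% c(-1L, 1L))) {
    stop_contract("desirability must be exactly +1 or -1")
  }
  if (!all(is.finite(df$cutoff))) stop_contract("cutoffs must be finite")
  structure(df[, c("c0", "cutoff", "desirability")],
            class = c("discretization_spec", "data.frame"))
}

#' Read a discretization spec from YAML
#'
#' Expects a `discretization:` mapping from activity-parameter level to
#' `{cutoff, desirability}` (or a bare mapping of the same shape).
#'
#' @param path YAML file path.
#' @return A [discretization_spec()].
#' @export
read_discretization_spec <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y$discretization %||% y
  discretization_spec(data.frame(
    c0 = names(y),
    cutoff = vapply(y, function(e) as.numeric(e$cutoff), numeric(1)),
    desirability = vapply(y, function(e) as.integer(e$desirability), integer(1)),
    stringsAsFactors = FALSE
  ))
}

#' Write a discretization spec to YAML
#' @param spec A [discretization_spec()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discretization_spec <- function(spec, path) {
  stopifnot(inherits(spec, "discretization_spec"))
  entries <- lapply(seq_len(nrow(spec)), function(i) {
    list(cutoff = spec$cutoff[i], desirability = spec$desirability[i])
  })
  names(entries) <- spec$c0
  yaml::write_yaml(list(discretization = entries), path)
  invisible(path)
}

#' Observed (desirability) function
#'
#' Binarizes an observed value against a cutoff under a desirability sign:
#' `1` iff (`v > cutoff` and `d = +1`) or (`v < cutoff` and `d = -1`), else
#' `0`. Inequalities are strict, so `v == cutoff` yields 0 for either sign.
#'
#' @param v Numeric vector of observed values.
#' @param cutoff Numeric cutoff(s), recycled against `v`.
#' @param d Desirability sign(s), each exactly +1 or -1, recycled.
#' @return Integer vector of 0/1.
#' @export
observed_function <- function(v, cutoff, d) {
  if (!all(d %in% c(-1, 1))) stop_contract("desirability must be exactly +1 or -1")
  stopifnot(is.numeric(v), is.numeric(cutoff), all(is.finite(v)), all(is.finite(cutoff)))
  as.integer((v > cutoff & d == 1) | (v < cutoff & d == -1))
}

#' Apply a discretization spec to an assay table
#'
#' Adds an `f_obs` column in `{0, 1}` computed row-wise by
#' [observed_function()] with the cutoff/desirability of the row's
#' activity-parameter label.
#'
#' @param table An [assay_table()].
#' @param spec A [discretization_spec()] covering every activity-parameter
#'   level present in the table.
#' @return The table with an `f_obs` column added.
#' @export
apply_discretization <- function(table, spec) {
  stopifnot(inherits(table, "assay_table"), inherits(spec, "discretization_spec"))
  c0_col <- if (flavour(table) == "drug") "c_d0" else "c_n0"
  idx <- match(table[[c0_col]], spec$c0)
  if (anyNA(idx)) {
    missing_lv <- unique(table[[c0_col]][is.na(idx)])
    stop_contract("activity-parameter level(s) missing from discretization spec: ",
                  paste(missing_lv, collapse = ", "))
  }
  table$f_obs <- observed_function(table$v, spec$cutoff[idx], spec$desirability[idx])
  table
}

#' Fit label-conditioned reference priors
#'
#' For each level of a grouping label, the reference (prior) probability of a
#' positive observed function: `p = n(f_obs = 1) / n` within the group.
#' Levels absent from the table are absent from the result; at lookup time
#' unseen levels fall back to the global positive rate.
#'
#' @param table An [assay_table()] carrying `f_obs`.
#' @param group_label Name of a label field of the table's flavour
#'   (default: the activity-parameter label).
#' @return A data frame of class `prior_table` with columns `level`, `n`,
#'   `n_pos`, `p`; attributes `group_label` and `global_p`.
#' @export
fit_priors <- function(table, group_label = NULL) {
  stopifnot(inherits(table, "assay_table"))
  if (is.null(table$f_obs)) stop_contract("table has no f_obs; run apply_discretization first")
  sch <- assay_schema(flavour(table))
  group_label <- group_label %||% sch$labels[1]
  if (!group_label %in% sch$labels) {
    stop_contract("group_label must be one of: ", paste(sch$labels, collapse = ", "))
  }
  g <- table[[group_label]]
  n <- tapply(table$f_obs, g, length)
  n_pos <- tapply(table$f_obs, g, sum)
  out <- data.frame(
    level = names(n),
    n = as.integer(n),
    n_pos = as.integer(n_pos),
    p = as.numeric(n_pos / n),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out,
    class = c("prior_table", "data.frame"),
    group_label = group_label,
    global_p = mean(table$f_obs)
  )
}

#' Look up priors with global fallback
#'
#' @param priors A [fit_priors()] result.
#' @param levels Character vector of label levels.
#' @return Numeric vector of prior probabilities; levels unseen at fit time
#'   get the global positive rate (logged).
#' @export
lookup_prior <- function(priors, levels) {
  stopifnot(inherits(priors, "prior_table"))
  idx <- match(as.character(levels), priors$level)
  p <- priors$p[idx]
  n_unseen <- sum(is.na(idx))
  if (n_unseen > 0) {
    ptml_log(n_unseen, " case(s) with unseen '", attr(priors, "group_label"),
             "' level; using global prior ", signif(attr(priors, "global_p"), 4))
    p[is.na(idx)] <- attr(priors, "global_p")
  }
  p
}

#' Joint reference prior for a drug-NP pair
#'
#' Combines the two marginal reference priors into the pair-level expected
#' probability of a desirable outcome. The default is the product of the
#' marginals (independence); `min` and `mean` are available alternatives.
#'
#' @param p_drug,p_np Probabilities in `[0, 1]`.
#' @param mode `"product"` (default), `"min"` or `"mean"`.
#' @return A probability in `[0, 1]`.
#' @export
joint_reference <- function(p_drug, p_np, mode = c("product", "min", "mean")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(p_drug), is.numeric(p_np))
  if (any(p_drug < 0 | p_drug > 1 | p_np < 0 | p_np > 1, na.rm = FALSE) ||
      anyNA(p_drug) || anyNA(p_np)) {
    stop_contract("marginal priors must lie in [0, 1]")
  }
  switch(mode,
    product = p_drug * p_np,
    min = pmin(p_drug, p_np),
    mean = (p_drug + p_np) / 2
  )
}
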