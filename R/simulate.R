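#' Prediction-grid level catalogues
#'
#' The combinatorial space for virtual-screening simulations: NP cores (with
#' representative length and core volume), cell lines (each tagged
#' `cytotoxicity` or `ecotoxicity`), NP shapes, coating agents (with McGowan
#' and van der Waals volumes), and drugs (with LOGP/PSA and the activity
#' parameter label).
#'
#' @param cores Data frame with columns `core`, `lnp`, `vnpu`.
#' @param cell_lines Data frame with columns `cell_line`, `assay_class`
#'   (`"cytotoxicity"` / `"ecotoxicity"`).
#' @param shapes Character vector.
#' @param coats Data frame with columns `coat`, `vxcoat`, `vvdwmgcoat`
#'   (finite).
#' @param drugs Data frame with columns `drug_id`, `logp`, `psa`, `c_d0`.
#' @param defaults Optional named list of default levels (`core`,
#'   `cell_line`, `shape`, `coat`, `drug_id`) used by [application_preset()];
#'   defaults to the first entry of each catalogue.
#' @param np_defaults Named list supplying the NP assay context for
#'   prediction rows: `t` (exposure/safety time, h), `c_n0` (NP activity
#'   parameter level), `c_n3` (measurement-conditions level).
#' @return A list of class `grid_levels`.
#' @export
grid_levels <- function(cores, cell_lines, shapes, coats, drugs,
                        defaults = list(),
                        np_defaults = list(t = 24, c_n0 = "CC50 (ug/ml)",
                                           c_n3 = "standard")) {
  stopifnot(is.data.frame(cores), all(c("core", "lnp", "vnpu") %in% names(cores)),
            is.data.frame(cell_lines),
            all(c("cell_line", "assay_class") %in% names(cell_lines)),
            is.character(shapes),
            is.data.frame(coats),
            all(c("coat", "vxcoat", "vvdwmgcoat") %in% names(coats)),
            is.data.frame(drugs),
            all(c("drug_id", "logp", "psa", "c_d0") %in% names(drugs)))
  if (anyDuplicated(cores$core) || anyDuplicated(cell_lines$cell_line) ||
      anyDuplicated(shapes) || anyDuplicated(coats$coat) ||
      anyDuplicated(drugs$drug_id)) {
    stop_contract("duplicate level within a catalogue")
  }
  if (nrow(cores) == 0 || nrow(cell_lines) == 0 || length(shapes) == 0 ||
      nrow(coats) == 0 || nrow(drugs) == 0) {
    stop_contract("every catalogue must be non-empty")
  }
  if (!all(is.finite(coats$vxcoat)) || !all(is.finite(coats$vvdwmgcoat))) {
    stop_contract("every coat needs finite volumes")
  }
  defaults <- utils::modifyList(list(
    core = cores$core[1], cell_line = cell_lines$cell_line[1],
    shape = shapes[1], coat = coats$coat[1], drug_id = drugs$drug_id[1]
  ), defaults)
  structure(list(cores = cores, cell_lines = cell_lines, shapes = shapes,
                 coats = coats, drugs = drugs, defaults = defaults,
                 np_defaults = np_defaults),
            class = "grid_levels")
}

#' @export
print.grid_levels <- function(x, ...) {
  cat(sprintf("<grid_levels> %d cores x %d cell lines x %d shapes x %d coats x %d drugs = %s combinations\n",
              nrow(x$cores), nrow(x$cell_lines), length(x$shapes),
              nrow(x$coats), nrow(x$drugs),
              format(grid_size(x), big.mark = ",")))
  invisible(x)
}

#' Total number of grid combinations
#'
#' `N = n(cores) * n(cell lines) * n(shapes) * n(coats) * n(drugs)`.
#'
#' @param levels A [grid_levels()].
#' @return The product of the catalogue sizes (double).
#' @export
grid_size <- function(levels) {
  stopifnot(inherits(levels, "grid_levels"))
  prod(as.numeric(c(nrow(levels$cores), nrow(levels$cell_lines),
                    length(levels$shapes), nrow(levels$coats),
                    nrow(levels$drugs))))
}

# Decode flat 1-based combination indices into one row index per catalogue
# (mixed-radix, drug fastest).
decode_grid_index <- function(k, sizes) {
  k <- k - 1
  out <- matrix(0L, nrow = length(k), ncol = length(sizes))
  for (j in rev(seq_along(sizes))) {
    out[, j] <- as.integer(k %% sizes[j]) + 1L
    k <- k %/% sizes[j]
  }
  out
}

#' Build a prediction set over a grid
#'
#' Samples `target_n` distinct grid combinations uniformly without
#' replacement (the full enumeration when `target_n` equals the grid size),
#' materializes each as a pseudo drug/NP assay pair, and computes the six
#' deviation features and the joint reference prior with previously fitted
#' statistics. Levels unseen at fit time use the global-mean / global-prior
#' fallback (logged).
#'
#' @param levels A [grid_levels()].
#' @param target_n Number of combinations.
#' @param seed Integer seed.
#' @param stats Fitted statistics: `attr(fused, "stats")` from [fuse()], or a
#'   list with `ma_drug`, `ma_np`, `priors_drug`, `priors_np`, `spec`,
#'   `prior_labels`, `joint_mode`.
#' @return A data frame of class `prediction_set`: `core`, `cell_line`,
#'   `assay_class`, `shape`, `coat`, `drug_id`, the feature columns, and
#'   `joint_ref`.
#' @export
build_prediction_set <- function(levels, target_n, seed = 42, stats) {
  stopifnot(inherits(levels, "grid_levels"))
  n_total <- grid_size(levels)
  if (target_n > n_total) {
    stop_contract("target_n (", target_n, ") exceeds grid size (",
                  format(n_total, big.mark = ","), ")")
  }
  if (n_total > .Machine$integer.max) stop_contract("grid too large to index")
  sizes <- c(nrow(levels$cores), nrow(levels$cell_lines), length(levels$shapes),
             nrow(levels$coats), nrow(levels$drugs))
  k <- if (target_n == n_total) seq_len(n_total) else {
    with_seed(seed, sample.int(as.integer(n_total), size = as.integer(target_n)))
  }
  idx <- decode_grid_index(k, sizes)

  drugs <- levels$drugs[idx[, 5], , drop = FALSE]
  # pseudo drug assay rows: only psa and c_d0 feed the model; the remaining
  # label fields are schema placeholders
  drug_df <- data.frame(
    drug_id = drugs$drug_id, v = 0, c_d0 = drugs$c_d0,
    stringsAsFactors = FALSE
  )
  for (lab in paste0("c_d", 1:8)) drug_df[[lab]] <- "unspecified"
  drug_df$logp <- drugs$logp
  drug_df$psa <- drugs$psa
  drug_tab <- assay_table(drug_df, "drug")

  cores <- levels$cores[idx[, 1], , drop = FALSE]
  coats <- levels$coats[idx[, 4], , drop = FALSE]
  cells <- levels$cell_lines[idx[, 2], , drop = FALSE]
  np_df <- data.frame(
    np_id = paste0("grid_", k), v = 0,
    c_n0 = levels$np_defaults$c_n0,
    c_n1 = cells$cell_line,
    c_n2 = levels$shapes[idx[, 3]],
    c_n3 = levels$np_defaults$c_n3 %||% "standard",
    c_n4 = coats$coat,
    core_type = cores$core,
    t = levels$np_defaults$t,
    lnp = cores$lnp, vnpu = cores$vnpu,
    vxcoat = coats$vxcoat, vvdwmgcoat = coats$vvdwmgcoat,
    stringsAsFactors = FALSE
  )
  np_tab <- assay_table(np_df, "np")

  spec <- stats$spec
  feat <- cbind(delta_features(drug_tab, stats$ma_drug, spec),
                delta_features(np_tab, stats$ma_np, spec))[, spec$name, drop = FALSE]
  p_d <- lookup_prior(stats$priors_drug, drug_tab[[stats$prior_labels[["drug"]]]])
  p_n <- lookup_prior(stats$priors_np, np_tab[[stats$prior_labels[["np"]]]])

  out <- data.frame(
    core = cores$core, cell_line = cells$cell_line,
    assay_class = cells$assay_class, shape = levels$shapes[idx[, 3]],
    coat = coats$coat, drug_id = drugs$drug_id,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(feat))
  out$joint_ref <- joint_reference(p_d, p_n, mode = stats$joint_mode %||% "product")
  rownames(out) <- NULL
  structure(out, class = c("prediction_set", "data.frame"))
}

#' Aggregate grid predictions into a binned heatmap
#'
#' Cells are (coat) x (core, cell line, shape); each holds the mean predicted
#' class-1 probability over the grid cases it contains and its support
#' (case count). Cells whose (cell line, coat) combination has fewer than
#' `min_support` occurrences in the reference assay data are masked (shown
#' white in a rendered figure) to avoid over-reading extrapolations. Rows
#' are ordered by coat McGowan volume ascending, ties broken by coat name.
#'
#' @param predictions A [build_prediction_set()] result with a probability
#'   column `p` added.
#' @param levels The [grid_levels()] used to build the predictions.
#' @param bins Two thresholds `c(low, high)` partitioning `[0, 1]`:
#'   `p >= high` is green, `low <= p < high` yellow, `p < low` red. Default
#'   `c(1/3, 2/3)`.
#' @param min_support Minimum (cell line, coat) occurrence count in
#'   `support_reference` for a cell to carry a bin; default 1.
#' @param support_reference Optional NP [assay_table()] (the original assay
#'   data) supplying the support counts; `NULL` disables masking.
#' @return A data frame of class `heatmap_report`: `coat`, `core`,
#'   `cell_line`, `shape`, `mean_p`, `support`, `bin` (factor
#'   green/yellow/red/masked).
#' @export
heatmap_aggregate <- function(predictions, levels, bins = c(1 / 3, 2 / 3),
                              min_support = 1, support_reference = NULL) {
  stopifnot(is.data.frame(predictions), "p" %in% names(predictions),
            inherits(levels, "grid_levels"), length(bins) == 2, bins[1] <= bins[2])
  if (any(predictions$p < 0 | predictions$p > 1)) {
    stop_contract("predicted probabilities must lie in [0, 1]")
  }
  key <- interaction(predictions$coat, predictions$core, predictions$cell_line,
                     predictions$shape, drop = TRUE, sep = "\r")
  agg <- data.frame(
    key = levels(key),
    mean_p = as.numeric(tapply(predictions$p, key, mean)),
    support = as.integer(tapply(predictions$p, key, length)),
    stringsAsFactors = FALSE
  )
  parts <- do.call(rbind, strsplit(agg$key, "\r", fixed = TRUE))
  agg$coat <- parts[, 1]
  agg$core <- parts[, 2]
  agg$cell_line <- parts[, 3]
  agg$shape <- parts[, 4]
  agg$key <- NULL

  agg$bin <- ifelse(agg$mean_p >= bins[2], "green",
                    ifelse(agg$mean_p >= bins[1], "yellow", "red"))
  if (!is.null(support_reference)) {
    stopifnot(inherits(support_reference, "assay_table"),
              flavour(support_reference) == "np")
    ref_key <- paste(support_reference$c_n1, support_reference$c_n4, sep = "\r")
    ref_counts <- table(ref_key)
    cell_key <- paste(agg$cell_line, agg$coat, sep = "\r")
    ref_n <- as.integer(ref_counts[cell_key])
    ref_n[is.na(ref_n)] <- 0L
    agg$bin[ref_n < min_support] <- "masked"
  }
  agg$bin <- factor(agg$bin, levels = c("green", "yellow", "red", "masked"))

  coat_order <- levels$coats[order(levels$coats$vxcoat, levels$coats$coat), "coat"]
  agg <- agg[order(match(agg$coat, coat_order), agg$core, agg$cell_line, agg$shape), ]
  rownames(agg) <- NULL
  agg <- agg[, c("coat", "core", "cell_line", "shape", "mean_p", "support", "bin")]
  structure(agg, class = c("heatmap_report", "data.frame"), bins = bins)
}

#' Single-variable scan presets
#'
#' Returns a grid holding every catalogue fixed at its default level except
#' the scanned one: `core_scan` varies NP cores (and shapes alongside, as
#' core selection includes morphology), `coat_scan` varies coating agents,
#' `drug_scan` varies drugs.
#'
#' @param mode `"core_scan"`, `"coat_scan"` or `"drug_scan"`.
#' @param base A [grid_levels()] supplying catalogues and defaults.
#' @param varied Optional replacement catalogue for the scanned dimension
#'   (same shape as in [grid_levels()]); default: the base catalogue.
#' @return A [grid_levels()].
#' @export
application_preset <- function(mode = c("core_scan", "coat_scan", "drug_scan"),
                               base, varied = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "grid_levels"))
  d <- base$defaults
  cores <- base$cores[base$cores$core == d$core, , drop = FALSE]
  cells <- base$cell_lines[base$cell_lines$cell_line == d$cell_line, , drop = FALSE]
  shapes <- d$shape
  coats <- base$coats[base$coats$coat == d$coat, , drop = FALSE]
  drugs <- base$drugs[base$drugs$drug_id == d$drug_id, , drop = FALSE]
  if (mode == "core_scan") {
    cores <- varied %||% base$cores
    shapes <- base$shapes
  } else if (mode == "coat_scan") {
    coats <- varied %||% base$coats
  } else {
    drugs <- varied %||% base$drugs
  }
  if ((is.data.frame(varied) && nrow(varied) == 0) ||
      (is.character(varied) && length(varied) == 0)) {
    stop_contract("varied catalogue must be non-empty")
  }
  grid_levels(cores, cells, shapes, coats, drugs,
              defaults = base$defaults, np_defaults = base$np_defaults)
}

#' Write a heatmap report as TSV
#' @param report A [heatmap_aggregate()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_heatmap_report <- function(report, path) {
  stopifnot(inherits(report, "heatmap_report"))
  utils::write.table(as.data.frame(report), path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
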