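#' Assemble a pipeline run configuration
#'
#' One configuration drives the full workflow: validate the two assay
#' tables, binarize observed values, sample and fuse drug-NP pairs (fitting
#' moving averages and priors leakage-safely), train classifiers, report
#' metrics, and optionally run a prediction-grid simulation.
#'
#' @param drug_table,np_table [assay_table()]s or CSV paths.
#' @param disc_drug,disc_np [discretization_spec()]s or YAML paths.
#' @param pt_features A [pt_feature_spec()] or YAML path; default the
#'   six-feature set.
#' @param fusion List: `target_n` (default 20000), `seed` (42), `combiner`,
#'   `joint_mode`, `train_frac` (0.75), `fit_on`.
#' @param models List: `algos` (default `"dt"`), `hyper` (named by algo).
#' @param simulate `NULL` to skip, or a list: `levels` (a [grid_levels()],
#'   or `NULL` to derive from the tables), `target_n` (default 20000),
#'   `seed`, `bins`, `min_support`.
#' @param out_dir Output directory for run artifacts; `NULL` writes nothing.
#' @return A list of class `run_config`.
#' @export
run_config <- function(drug_table, np_table, disc_drug, disc_np,
                       pt_features = default_pt_features(),
                       fusion = list(), models = list(), simulate = list(),
                       out_dir = NULL) {
  fusion <- utils::modifyList(list(target_n = 20000, seed = 42,
                                   combiner = "and", joint_mode = "product",
                                   train_frac = 0.75, fit_on = "train"), fusion)
  models <- utils::modifyList(list(algos = "dt", hyper = list()), models)
  if (!is.null(simulate)) {
    simulate <- utils::modifyList(list(levels = NULL, target_n = 20000,
                                       seed = 42, bins = c(1 / 3, 2 / 3),
                                       min_support = 1), simulate)
  }
  structure(list(drug_table = drug_table, np_table = np_table,
                 disc_drug = disc_drug, disc_np = disc_np,
                 pt_features = pt_features, fusion = fusion, models = models,
                 simulate = simulate, out_dir = out_dir),
            class = "run_config")
}

resolve_table <- function(x, flavour) {
  if (inherits(x, "assay_table")) x else read_assay_table(x, flavour)
}

resolve_disc <- function(x) {
  if (inherits(x, "discretization_spec")) x else read_discretization_spec(x)
}

config_fingerprint <- function(cfg) {
  plain <- rapply(unclass(cfg), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }, how = "replace")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the end-to-end workflow
#'
#' Executes the stages in order — validate, discretize, sample pairs, fuse,
#' train, evaluate, simulate — and records a machine-readable manifest with
#' per-stage row counts, seeds and a configuration fingerprint. Any stage
#' failure aborts with the stage name and cause. With an `out_dir`, the
#' fused table (CSV), the metrics report (TSV), the heatmap (TSV) and the
#' manifest (JSON) are written.
#'
#' @param cfg A [run_config()].
#' @return A list of class `run_result`: `manifest`, `fused`, `model`s,
#'   `reports`, `heatmap`, `artifact` paths.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  manifest <- list(config_hash = config_fingerprint(cfg),
                   seed = cfg$fusion$seed, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    res
  }
  mark <- function(name, counts) {
    manifest$stages[[name]] <<- c(list(status = "complete"), counts)
  }

  drug <- stage("validate", resolve_table(cfg$drug_table, "drug"))
  np <- stage("validate", resolve_table(cfg$np_table, "np"))
  mark("validate", list(drug_rows = nrow(drug), np_rows = nrow(np),
                        drug_dropped = attr(drug, "n_dropped"),
                        np_dropped = attr(np, "n_dropped")))

  drug <- stage("discretize", apply_discretization(drug, resolve_disc(cfg$disc_drug)))
  np <- stage("discretize", apply_discretization(np, resolve_disc(cfg$disc_np)))
  mark("discretize", list(drug_positive = sum(drug$f_obs), np_positive = sum(np$f_obs)))

  spec <- if (inherits(cfg$pt_features, "pt_feature_spec")) cfg$pt_features else {
    read_pt_feature_spec(cfg$pt_features)
  }
  pairs <- stage("sample_pairs", sample_pairs(nrow(drug), nrow(np),
                                              cfg$fusion$target_n, cfg$fusion$seed))
  mark("sample_pairs", list(pairs = nrow(pairs)))

  fused <- stage("fuse", fuse(drug, np, pairs, spec,
                              combiner = cfg$fusion$combiner,
                              joint_mode = cfg$fusion$joint_mode,
                              train_frac = cfg$fusion$train_frac,
                              seed = cfg$fusion$seed,
                              fit_on = cfg$fusion$fit_on))
  mark("fuse", list(cases = nrow(fused),
                    train = sum(fused$partition == "t"),
                    valid = sum(fused$partition == "v"),
                    positives = sum(fused$y)))

  algos <- cfg$models$algos
  fits <- stage("train", lapply(stats::setNames(algos, algos), function(a) {
    train_classifier(fused, a, hyper = cfg$models$hyper[[a]] %||% list())
  }))
  mark("train", list(models = length(fits)))

  reports <- stage("evaluate", {
    out <- list()
    for (a in algos) {
      out[[paste0(a, "_t")]] <- evaluate(fits[[a]], fused, "t")
      out[[paste0(a, "_v")]] <- evaluate(fits[[a]], fused, "v")
    }
    out
  })
  mark("evaluate", list(reports = length(reports)))

  heatmap <- NULL
  if (!is.null(cfg$simulate)) {
    heatmap <- stage("simulate", {
      levels <- cfg$simulate$levels %||% levels_from_tables(drug, np)
      pred <- build_prediction_set(levels,
                                   min(cfg$simulate$target_n, grid_size(levels)),
                                   seed = cfg$simulate$seed,
                                   stats = attr(fused, "stats"))
      pred$p <- predict_proba(fits[[algos[1]]], pred)
      heatmap_aggregate(pred, levels, bins = cfg$simulate$bins,
                        min_support = cfg$simulate$min_support,
                        support_reference = np)
    })
    mark("simulate", list(cells = nrow(heatmap),
                          masked = sum(heatmap$bin == "masked")))
  } else {
    mark("simulate", list(cells = 0L, skipped = TRUE))
  }

  artifacts <- list()
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    artifacts$fused <- file.path(cfg$out_dir, "fused.csv")
    write_fused_dataset(fused, artifacts$fused)
    artifacts$report <- file.path(cfg$out_dir, "report.tsv")
    utils::write.table(metrics_table(reports), artifacts$report, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(heatmap)) {
      artifacts$heatmap <- file.path(cfg$out_dir, "heatmap.tsv")
      write_heatmap_report(heatmap, artifacts$heatmap)
    }
    artifacts$manifest <- file.path(cfg$out_dir, "manifest.json")
    jsonlite::write_json(manifest, artifacts$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }

  structure(list(manifest = manifest, fused = fused, models = fits,
                 reports = reports, heatmap = heatmap, artifacts = artifacts),
            class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result> stages:\n")
  for (nm in names(x$manifest$stages)) {
    st <- x$manifest$stages[[nm]]
    counts <- st[setdiff(names(st), "status")]
    cat(sprintf("  %-12s %s  %s\n", nm, st$status,
                paste(names(counts), unlist(counts), sep = "=", collapse = " ")))
  }
  for (r in x$reports) print(r)
  invisible(x)
}
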