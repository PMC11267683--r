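#' Perturbation-theory feature specification
#'
#' Each deviation feature is a descriptor minus its moving average over the
#' assays sharing the row's level of a conditioning label:
#' `delta = D - <D | label level>`. The default is the six-variable set used
#' for delivery-system models: the drug polar-surface-area deviation
#' conditioned on the drug activity parameter, and five NP deviations (safety
#' time, NP length, core volume, coat McGowan volume, coat van der Waals
#' volume) conditioned on the NP activity parameter.
#'
#' @param features Data frame with columns `name`, `flavour` (`drug`/`np`),
#'   `descriptor`, `label_field`.
#' @return `features` with class `pt_feature_spec`.
#' @export
pt_feature_spec <- function(features) {
  stopifnot(is.data.frame(features),
            all(c("name", "flavour", "descriptor", "label_field") %in% names(features)))
  features <- features[, c("name", "flavour", "descriptor", "label_field")]
  for (col in names(features)) features[[col]] <- as.character(features[[col]])
  if (anyDuplicated(features$name)) stop_contract("feature names must be unique")
  if (!all(features$flavour %in% c("drug", "np"))) {
    stop_contract("flavour must be 'drug' or 'np'")
  }
  for (i in seq_len(nrow(features))) {
    sch <- assay_schema(features$flavour[i])
    if (!features$descriptor[i] %in% setdiff(sch$numeric, "v")) {
      stop_contract("unknown ", features$flavour[i], " descriptor: ", features$descriptor[i])
    }
    if (!features$label_field[i] %in% sch$labels) {
      stop_contract("unknown ", features$flavour[i], " label field: ", features$label_field[i])
    }
  }
  structure(features, class = c("pt_feature_spec", "data.frame"))
}

#' @rdname pt_feature_spec
#' @export
default_pt_features <- function() {
  pt_feature_spec(data.frame(
    name = c("delta_psa", "delta_t", "delta_lnp", "delta_vnpu",
             "delta_vxcoat", "delta_vvdwmgcoat"),
    flavour = c("drug", rep("np", 5)),
    descriptor = c("psa", "t", "lnp", "vnpu", "vxcoat", "vvdwmgcoat"),
    label_field = c("c_d0", rep("c_n0", 5)),
    stringsAsFactors = FALSE
  ))
}

#' Read / write a feature spec as YAML
#'
#' The YAML block `pt_features:` lists entries with `name`, `flavour`,
#' `descriptor`, `label_field`.
#'
#' @param path YAML file path.
#' @return A [pt_feature_spec()].
#' @export
read_pt_feature_spec <- function(path) {
  y <- yaml::read_yaml(path)
  y <- y$pt_features %||% y
  pt_feature_spec(do.call(rbind, lapply(y, function(e) {
    data.frame(name = e$name, flavour = e$flavour, descriptor = e$descriptor,
               label_field = e$label_field, stringsAsFactors = FALSE)
  })))
}

#' @rdname read_pt_feature_spec
#' @param spec A [pt_feature_spec()].
#' @export
write_pt_feature_spec <- function(spec, path) {
  stopifnot(inherits(spec, "pt_feature_spec"))
  entries <- lapply(seq_len(nrow(spec)), function(i) as.list(as.data.frame(spec)[i, ]))
  yaml::write_yaml(list(pt_features = entries), path)
  invisible(path)
}

#' Fit label-conditioned moving averages
#'
#' For every feature of the table's flavour, the mean of its descriptor over
#' the rows sharing each level of the conditioning label, plus the global
#' descriptor mean (the fallback for levels unseen at fit time).
#'
#' @param table An [assay_table()].
#' @param spec A [pt_feature_spec()]; only rows matching the table's flavour
#'   are fitted.
#' @return A list of class `moving_average_table`, one entry per feature:
#'   `list(descriptor, label_field, means, global)`.
#' @export
fit_moving_averages <- function(table, spec) {
  stopifnot(inherits(table, "assay_table"), inherits(spec, "pt_feature_spec"))
  if (nrow(table) == 0) stop_contract("cannot fit moving averages on an empty table")
  spec <- spec[spec$flavour == flavour(table), , drop = FALSE]
  out <- lapply(seq_len(nrow(spec)), function(i) {
    d <- table[[spec$descriptor[i]]]
    g <- table[[spec$label_field[i]]]
    means <- tapply(d, g, mean)
    list(
      descriptor = spec$descriptor[i],
      label_field = spec$label_field[i],
      means = stats::setNames(as.numeric(means), names(means)),
      global = mean(d)
    )
  })
  names(out) <- spec$name
  structure(out, class = "moving_average_table", flavour = flavour(table),
            n_fit = nrow(table))
}

#' @export
print.moving_average_table <- function(x, ...) {
  cat(sprintf("<moving_average_table [%s]> fitted on %d rows\n",
              attr(x, "flavour"), attr(x, "n_fit")))
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s | %s (%d levels, global %.4g)\n", nm,
                x[[nm]]$descriptor, x[[nm]]$label_field,
                length(x[[nm]]$means), x[[nm]]$global))
  }
  invisible(x)
}

#' Perturbation-theory deviation features
#'
#' `delta = D - <D | label level>` per row; rows whose label level was unseen
#' when the moving averages were fitted use the global descriptor mean
#' (logged). Fitting on a training partition and applying to validation or
#' prediction rows is leakage-safe: the stored means never change.
#'
#' @param table An [assay_table()] of the same flavour the averages were
#'   fitted on.
#' @param ma A [fit_moving_averages()] result.
#' @param spec A [pt_feature_spec()]; only rows matching the table's flavour
#'   are computed.
#' @return Numeric matrix, `nrow(table)` rows, one column per feature.
#' @export
delta_features <- function(table, ma, spec) {
  stopifnot(inherits(table, "assay_table"), inherits(ma, "moving_average_table"),
            inherits(spec, "pt_feature_spec"))
  if (attr(ma, "flavour") != flavour(table)) {
    stop_contract("moving averages were fitted on a ", attr(ma, "flavour"), " table")
  }
  spec <- spec[spec$flavour == flavour(table), , drop = FALSE]
  if (!all(spec$name %in% names(ma))) {
    stop_contract("moving averages missing feature(s): ",
                  paste(setdiff(spec$name, names(ma)), collapse = ", "))
  }
  out <- matrix(NA_real_, nrow = nrow(table), ncol = nrow(spec),
                dimnames = list(NULL, spec$name))
  for (i in seq_len(nrow(spec))) {
    entry <- ma[[spec$name[i]]]
    mean_for_row <- entry$means[table[[entry$label_field]]]
    n_unseen <- sum(is.na(mean_for_row))
    if (n_unseen > 0) {
      ptml_log(n_unseen, " row(s) with unseen '", entry$label_field,
               "' level for ", spec$name[i], "; using global mean")
      mean_for_row[is.na(mean_for_row)] <- entry$global
    }
    out[, i] <- table[[entry$descriptor]] - as.numeric(mean_for_row)
  }
  out
}
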