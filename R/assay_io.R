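#' Canonical assay-table schemas
#'
#' Column catalogues for the two assay flavours. A drug assay row holds an
#' observed activity value `v`, nine condition labels `c_d0` (activity
#' parameter) through `c_d8` (target mapping), and two molecular descriptors
#' (`logp`, `psa`). A nanoparticle (NP) assay row holds `v`, five condition
#' labels `c_n0` (activity parameter) through `c_n4` (coating agent), a core
#' composition label, and five numeric descriptors: exposure/safety time `t`
#' (h), NP length `lnp` (nm), core volume `vnpu` (nm^3), and the coat McGowan
#' characteristic volume `vxcoat` and van der Waals volume `vvdwmgcoat`
#' (descriptor-native units).
#'
#' @param flavour `"drug"` or `"np"`.
#' @return A list with character vectors `id`, `labels`, `numeric`, `all`.
#' @export
assay_schema <- function(flavour = c("drug", "np")) {
  flavour <- match.arg(flavour)
  if (flavour == "drug") {
    labels <- paste0("c_d", 0:8)
    list(
      id = "drug_id",
      labels = labels,
      numeric = c("v", "logp", "psa"),
      positive = character(0),
      all = c("drug_id", "v", labels, "logp", "psa")
    )
  } else {
    labels <- c(paste0("c_n", 0:4), "core_type")
    list(
      id = "np_id",
      labels = labels,
      numeric = c("v", "t", "lnp", "vnpu", "vxcoat", "vvdwmgcoat"),
      positive = c("lnp", "vnpu"),
      all = c("np_id", "v", labels, "t", "lnp", "vnpu", "vxcoat", "vvdwmgcoat")
    )
  }
}

#' Construct and validate an assay table
#'
#' Validates a data frame against the canonical schema for its flavour. Rows
#' with a non-finite numeric field, an empty label, an empty id, or (NP only)
#' a non-positive length/core volume are dropped and counted in the log;
#' labels are never imputed. Duplicate rows are kept: repeated assays of the
#' same entity are real observations.
#'
#' @param df A data frame holding the canonical columns (see [assay_schema()]).
#' @param flavour `"drug"` or `"np"`.
#' @return The validated data frame with class `assay_table` and a `flavour`
#'   attribute; `attr(x, "n_dropped")` counts removed rows.
#' @export
assay_table <- function(df, flavour = c("drug", "np")) {
  flavour <- match.arg(flavour)
  sch <- assay_schema(flavour)
  missing_cols <- setdiff(sch$all, names(df))
  if (length(missing_cols) > 0) {
    stop_contract("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, sch$all, drop = FALSE]
  for (col in sch$labels) df[[col]] <- as.character(df[[col]])
  df[[sch$id]] <- as.character(df[[sch$id]])
  for (col in sch$numeric) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  ok <- rep(TRUE, nrow(df))
  for (col in sch$numeric) ok <- ok & is.finite(df[[col]])
  for (col in sch$positive) ok <- ok & !is.na(df[[col]]) & df[[col]] > 0
  for (col in sch$labels) ok <- ok & !is.na(df[[col]]) & nzchar(df[[col]])
  ok <- ok & !is.na(df[[sch$id]]) & nzchar(df[[sch$id]])

  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    ptml_log(n_dropped, " row(s) dropped during ", flavour, "-table validation")
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0) stop_contract("empty ", flavour, " assay table after validation")
  rownames(df) <- NULL
  structure(df,
    class = c("assay_table", "data.frame"),
    flavour = flavour, n_dropped = n_dropped
  )
}

#' @export
flavour <- function(x) attr(x, "flavour")

#' Read an assay table from CSV
#'
#' Reads a comma-delimited UTF-8 file with a header row, optionally renames
#' source headers to canonical names, and validates with [assay_table()].
#'
#' @param path Path to a CSV file.
#' @param flavour `"drug"` or `"np"`.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the headers used in the file, e.g. `c(logp = "XLogP")`.
#' @return An [assay_table()].
#' @export
read_assay_table <- function(path, flavour = c("drug", "np"), column_map = NULL) {
  flavour <- match.arg(flavour)
  if (!file.exists(path)) stop_contract("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    stopifnot(is.character(column_map), !is.null(names(column_map)))
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(df)) {
        stop_contract("column_map source header not in file: ", src)
      }
      names(df)[names(df) == src] <- canon
    }
  }
  assay_table(df, flavour)
}

#' Write an assay table to CSV
#'
#' Canonical columns only, comma-delimited, UTF-8; round-trips through
#' [read_assay_table()].
#'
#' @param table An [assay_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assay_table <- function(table, path) {
  stopifnot(inherits(table, "assay_table"))
  sch <- assay_schema(flavour(table))
  utils::write.csv(as.data.frame(table)[, sch$all, drop = FALSE], path,
                   row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Summarize an assay table
#'
#' Row count, distinct entities, mean assays per entity (rows / entities,
#' reported to 2 decimals), and per-label level counts.
#'
#' @param table An [assay_table()].
#' @return A list of class `assay_summary` with elements `flavour`, `n_rows`,
#'   `n_entities`, `assays_per_entity`, `label_counts`.
#' @export
summarize_table <- function(table) {
  stopifnot(inherits(table, "assay_table"))
  if (nrow(table) == 0) stop_contract("empty table")
  sch <- assay_schema(flavour(table))
  ids <- table[[sch$id]]
  label_counts <- lapply(sch$labels, function(col) {
    tab <- table(table[[col]])
    stats::setNames(as.integer(tab), names(tab))
  })
  names(label_counts) <- sch$labels
  structure(list(
    flavour = flavour(table),
    n_rows = nrow(table),
    n_entities = length(unique(ids)),
    assays_per_entity = round(nrow(table) / length(unique(ids)), 2),
    label_counts = label_counts
  ), class = "assay_summary")
}

#' @export
print.assay_summary <- function(x, ...) {
  cat(sprintf("%s assay table: %d assays, %d entities, %.2f assays/entity\n",
              x$flavour, x$n_rows, x$n_entities, x$assays_per_entity))
  for (lab in names(x$label_counts)) {
    cat(sprintf("  %-12s %d level(s)\n", lab, length(x$label_counts[[lab]])))
  }
  invisible(x)
}

#' @export
print.assay_table <- function(x, ...) {
  cat(sprintf("<assay_table [%s]> %d rows\n", flavour(x), nrow(x)))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# Subsetting keeps the class and flavour (base [ would drop attributes).
#' @export
`[.assay_table` <- function(x, i, j, drop = FALSE) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "flavour") <- attr(x, "flavour")
    class(out) <- c("assay_table", "data.frame")
  }
  out
}
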