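#' Default demo discretization specs
#'
#' Endpoint cutoffs and desirability signs shipped with the synthetic data.
#' Drug endpoints are potency measures (lower is better for concentration
#' endpoints, higher for percentage responses); NP endpoints are safety
#' measures (a higher tolerated concentration or viability is desirable,
#' higher mortality is not).
#'
#' @param flavour `"drug"` or `"np"`.
#' @return A [discretization_spec()].
#' @export
default_discretization <- function(flavour = c("drug", "np")) {
  flavour <- match.arg(flavour)
  if (flavour == "drug") {
    discretization_spec(data.frame(
      c0 = c("IC50 (nM)", "Ki (nM)", "EC50 (nM)", "Inhibition (%)", "Activity (%)"),
      cutoff = c(1000, 500, 2000, 50, 50),
      desirability = c(-1L, -1L, -1L, 1L, 1L),
      stringsAsFactors = FALSE
    ))
  } else {
    discretization_spec(data.frame(
      c0 = c("CC50 (ug/ml)", "TC50 (ug/ml)", "LC50 (mg/l)", "Viability (%)",
             "Mortality (%)"),
      cutoff = c(40, 30, 10, 80, 20),
      desirability = c(1L, 1L, 1L, 1L, -1L),
      stringsAsFactors = FALSE
    ))
  }
}

#' Cell-line / organism catalogue for the synthetic NP data
#'
#' Cytotoxicity cell lines and ecotoxicity organisms handled as levels of
#' the same cell-line label, tagged by assay class.
#'
#' @return Data frame with columns `cell_line`, `assay_class`.
#' @export
default_np_cell_lines <- function() {
  data.frame(
    cell_line = c("HepG2", "A549", "L929", "MCF-7", "HeLa", "RAW264.7",
                  "SH-SY5Y", "NIH-3T3", "Caco-2", "HUVEC",
                  "Vibrio fischeri", "Danio rerio (embryos)",
                  "Daphnia pulex (adults)", "Lycopersicon esculentum",
                  "Oryzias latipes (embryos)"),
    assay_class = c(rep("cytotoxicity", 10), rep("ecotoxicity", 5)),
    stringsAsFactors = FALSE
  )
}

default_coat_catalog <- function() {
  c("CTAB", "PVA", "PVP", "PEG", "potato starch", "chitosan", "citrate",
    "dextran", "oleic acid", "PMAO", "silica", "PLGA", "alginate",
    "gelatin", "Tween-80", "none")
}

default_shape_catalog <- function() {
  c("spherical", "irregular", "elliptical", "cuboctahedral", "octahedral")
}

default_core_catalog <- function() {
  c("Fe3O4", "Fe2O3", "CoFe2O4", "ZnFe2O4", "Fe")
}

#' Synthetic-data configuration
#'
#' Defaults reproduce the study conditions of the modelled corpus: 4403 drug
#' assays over 2566 drugs (1.72 assays/drug) and 260 NP assays over 31 NPs
#' (8.39 assays/NP), with baseline positive rates chosen so the fused
#' class-1 prevalence under the `and` combiner is about 7%. Assay totals are
#' allocated exactly (one assay minimum per entity, remainder multinomial);
#' set a total to `NULL` to draw per-entity counts as shifted Poisson with
#' the configured mean instead.
#'
#' @param seed Integer master seed.
#' @param n_drugs,n_nps Entity counts.
#' @param n_drug_assays,n_np_assays Exact assay totals (or `NULL`).
#' @param assays_per_drug_mean,assays_per_np_mean Mean assay counts used
#'   when the totals are `NULL`.
#' @param p1_drug,p1_np Baseline positive rates in (0, 1).
#' @param signal Named log-odds weights on the standardized descriptor
#'   deviations, one per deviation feature; `0` disables a feature's signal.
#' @param descriptors Named list of distribution parameters (see source).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 42,
                         n_drugs = 2566, n_drug_assays = 4403,
                         n_nps = 31, n_np_assays = 260,
                         assays_per_drug_mean = 1.72,
                         assays_per_np_mean = 8.39,
                         p1_drug = 0.30, p1_np = 0.23,
                         signal = c(delta_psa = -1.5, delta_t = 1.0,
                                    delta_lnp = -1.0, delta_vnpu = -0.8,
                                    delta_vxcoat = 1.2, delta_vvdwmgcoat = 1.5),
                         descriptors = list(
                           logp = c(mean = 2.5, sd = 1.5),
                           psa = c(meanlog = log(75), sdlog = 0.45),
                           t = c(mean = 48, sd = 24),
                           lnp = c(meanlog = log(50), sdlog = 0.5),
                           vnpu = c(meanlog = log(2e4), sdlog = 0.8),
                           vxcoat = c(meanlog = log(200), sdlog = 0.6)
                         )) {
  cfg <- list(seed = seed, n_drugs = n_drugs, n_drug_assays = n_drug_assays,
              n_nps = n_nps, n_np_assays = n_np_assays,
              assays_per_drug_mean = assays_per_drug_mean,
              assays_per_np_mean = assays_per_np_mean,
              p1_drug = p1_drug, p1_np = p1_np,
              signal = signal, descriptors = descriptors)
  stopifnot(n_drugs >= 1, n_nps >= 1,
            assays_per_drug_mean >= 1, assays_per_np_mean >= 1,
            p1_drug > 0, p1_drug < 1, p1_np > 0, p1_np < 1)
  if (!is.null(n_drug_assays)) stopifnot(n_drug_assays >= n_drugs)
  if (!is.null(n_np_assays)) stopifnot(n_np_assays >= n_nps)
  structure(cfg, class = "synth_config")
}

# Per-entity assay counts: exact total (min 1 each, remainder multinomial)
# or shifted Poisson around the configured mean.
allocate_counts <- function(n_entities, total, mean_per_entity) {
  if (!is.null(total)) {
    extra <- stats::rmultinom(1, size = total - n_entities,
                              prob = rep(1, n_entities))[, 1]
    as.integer(1L + extra)
  } else {
    as.integer(1L + stats::rpois(n_entities, mean_per_entity - 1))
  }
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Solve the logistic intercept so the marginal positive rate equals the
# configured baseline even when a signal is planted (mean of plogis over the
# signal distribution, not plogis of the mean).
calibrate_intercept <- function(eta, p_target) {
  if (all(eta == 0)) return(stats::qlogis(p_target))
  stats::uniroot(function(b) mean(stats::plogis(b + eta)) - p_target,
                 interval = stats::qlogis(p_target) + c(-25, 25))$root
}

# Draw v so that observed_function(v, cutoff, d) reproduces the latent
# Bernoulli outcome exactly: positives sit strictly on the desirable side.
draw_v <- function(z, cutoff, d) {
  u <- stats::rexp(length(z)) * pmax(abs(cutoff), 1) / 2
  side <- ifelse(z == 1L, d, -d)
  cutoff + side * u
}

#' Generate a synthetic drug-assay table
#'
#' Drug-level descriptors (LOGP normal, PSA lognormal), labels uniform over
#' fixed catalogues, and observed values generated on a latent scale: each
#' assay's positive probability is the baseline rate shifted by the planted
#' log-odds on the standardized PSA deviation, and `v` is then placed on the
#' corresponding side of its endpoint's cutoff so that the shipped
#' discretization recovers the latent outcome exactly. Fully reproducible
#' per seed.
#'
#' @param cfg A [synth_config()].
#' @return A drug [assay_table()].
#' @export
gen_drug_assays <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  spec <- default_discretization("drug")
  with_seed(cfg$seed, {
    counts <- allocate_counts(cfg$n_drugs, cfg$n_drug_assays,
                              cfg$assays_per_drug_mean)
    drug_ids <- sprintf("DRUG%05d", seq_len(cfg$n_drugs))
    dpar <- cfg$descriptors
    logp <- stats::rnorm(cfg$n_drugs, dpar$logp["mean"], dpar$logp["sd"])
    psa <- stats::rlnorm(cfg$n_drugs, dpar$psa["meanlog"], dpar$psa["sdlog"])

    n <- sum(counts)
    idx <- rep(seq_len(cfg$n_drugs), counts)
    df <- data.frame(
      drug_id = drug_ids[idx],
      v = 0,
      c_d0 = sample(spec$c0, n, replace = TRUE),
      c_d1 = sample(sprintf("TP%02d", 1:12), n, replace = TRUE),
      c_d2 = sample(sprintf("CL%02d", 1:8), n, replace = TRUE),
      c_d3 = sample(c("Homo sapiens", "Mus musculus", "Rattus norvegicus",
                      "Cavia porcellus", "Macaca mulatta"), n, replace = TRUE),
      c_d4 = sample(c("SINGLE PROTEIN", "CELL-LINE", "ORGANISM"), n, replace = TRUE),
      c_d5 = sample(c("B", "F", "A", "T"), n, replace = TRUE),
      c_d6 = sample(c("Expert", "Autocuration"), n, replace = TRUE),
      c_d7 = sample(sprintf("CS%d", 6:9), n, replace = TRUE),
      c_d8 = sample(c("Direct", "Homologue", "Variant"), n, replace = TRUE),
      logp = logp[idx],
      psa = psa[idx],
      stringsAsFactors = FALSE
    )
    w <- cfg$signal[["delta_psa"]] %||% 0
    eta <- w * standardize(df$psa)
    z <- stats::rbinom(n, 1, stats::plogis(calibrate_intercept(eta, cfg$p1_drug) + eta))
    m <- match(df$c_d0, spec$c0)
    df$v <- draw_v(z, spec$cutoff[m], spec$desirability[m])
    assay_table(df, "drug")
  })
}

#' Generate a synthetic NP-assay table
#'
#' NP-level core type, shape, length and core volume; coat-level McGowan and
#' van der Waals volumes shared by every assay of the same coating agent;
#' per-assay exposure time, cell line and measurement conditions. The
#' planted log-odds act on the standardized deviations of the five NP
#' descriptors; `v` encodes the latent outcome through the shipped
#' discretization exactly as in [gen_drug_assays()].
#'
#' @param cfg A [synth_config()].
#' @return An NP [assay_table()].
#' @export
gen_np_assays <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  spec <- default_discretization("np")
  with_seed(cfg$seed + 1L, {
    counts <- allocate_counts(cfg$n_nps, cfg$n_np_assays, cfg$assays_per_np_mean)
    np_ids <- sprintf("NP%03d", seq_len(cfg$n_nps))
    dpar <- cfg$descriptors
    cores <- sample(default_core_catalog(), cfg$n_nps, replace = TRUE)
    lnp <- stats::rlnorm(cfg$n_nps, dpar$lnp["meanlog"], dpar$lnp["sdlog"])
    vnpu <- stats::rlnorm(cfg$n_nps, dpar$vnpu["meanlog"], dpar$vnpu["sdlog"])

    coat_names <- default_coat_catalog()
    coat_vx <- stats::rlnorm(length(coat_names), dpar$vxcoat["meanlog"],
                             dpar$vxcoat["sdlog"])
    coat_vvdw <- coat_vx * stats::runif(length(coat_names), 0.65, 0.9)

    n <- sum(counts)
    idx <- rep(seq_len(cfg$n_nps), counts)
    cells <- default_np_cell_lines()
    coat_idx <- sample(seq_along(coat_names), n, replace = TRUE)
    df <- data.frame(
      np_id = np_ids[idx],
      v = 0,
      c_n0 = sample(spec$c0, n, replace = TRUE),
      c_n1 = sample(cells$cell_line, n, replace = TRUE),
      c_n2 = sample(default_shape_catalog(), n, replace = TRUE),
      c_n3 = sample(c("standard", "serum-free", "sonicated", "FBS 10%"),
                    n, replace = TRUE),
      c_n4 = coat_names[coat_idx],
      core_type = cores[idx],
      t = pmax(1, stats::rnorm(n, dpar$t["mean"], dpar$t["sd"])),
      lnp = lnp[idx],
      vnpu = vnpu[idx],
      vxcoat = coat_vx[coat_idx],
      vvdwmgcoat = coat_vvdw[coat_idx],
      stringsAsFactors = FALSE
    )
    w <- cfg$signal
    eta <- (w[["delta_t"]] %||% 0) * standardize(df$t) +
      (w[["delta_lnp"]] %||% 0) * standardize(df$lnp) +
      (w[["delta_vnpu"]] %||% 0) * standardize(df$vnpu) +
      (w[["delta_vxcoat"]] %||% 0) * standardize(df$vxcoat) +
      (w[["delta_vvdwmgcoat"]] %||% 0) * standardize(df$vvdwmgcoat)
    z <- stats::rbinom(n, 1, stats::plogis(calibrate_intercept(eta, cfg$p1_np) + eta))
    m <- match(df$c_n0, spec$c0)
    df$v <- draw_v(z, spec$cutoff[m], spec$desirability[m])
    assay_table(df, "np")
  })
}

#' Grid catalogues derived from assay tables
#'
#' Builds a [grid_levels()] whose catalogues are the levels observed in the
#' given tables: cores with their mean length/volume, cell lines tagged by
#' assay class, shapes, coats with their shared volumes, and drugs with
#' their descriptors and modal activity parameter.
#'
#' @param drug_table,np_table Assay tables.
#' @param cell_classes Data frame mapping `cell_line` to `assay_class`;
#'   defaults to [default_np_cell_lines()] with unknown levels tagged
#'   `cytotoxicity`.
#' @return A [grid_levels()].
#' @export
levels_from_tables <- function(drug_table, np_table,
                               cell_classes = default_np_cell_lines()) {
  stopifnot(inherits(drug_table, "assay_table"), inherits(np_table, "assay_table"))
  cores <- stats::aggregate(cbind(lnp, vnpu) ~ core_type, data = np_table, FUN = mean)
  names(cores)[1] <- "core"
  cls <- unique(np_table$c_n1)
  cell_lines <- data.frame(
    cell_line = cls,
    assay_class = cell_classes$assay_class[match(cls, cell_classes$cell_line)],
    stringsAsFactors = FALSE
  )
  cell_lines$assay_class[is.na(cell_lines$assay_class)] <- "cytotoxicity"
  coats <- unique(as.data.frame(np_table)[, c("c_n4", "vxcoat", "vvdwmgcoat")])
  names(coats)[1] <- "coat"
  first <- !duplicated(drug_table$drug_id)
  drugs <- data.frame(
    drug_id = drug_table$drug_id[first],
    logp = drug_table$logp[first],
    psa = drug_table$psa[first],
    c_d0 = drug_table$c_d0[first],
    stringsAsFactors = FALSE
  )
  grid_levels(cores, cell_lines, unique(np_table$c_n2), coats, drugs,
              np_defaults = list(t = round(mean(np_table$t)),
                                 c_n0 = names(sort(table(np_table$c_n0),
                                                   decreasing = TRUE))[1],
                                 c_n3 = names(sort(table(np_table$c_n3),
                                                   decreasing = TRUE))[1]))
}

#' Write a self-consistent synthetic fixture set
#'
#' Generates drug and NP tables sized for sub-minute end-to-end runs
#' (default about 2000 drug assays and 200 NP assays, fused target 20,000)
#' and writes the CSV tables plus the YAML discretization and feature specs
#' the pipeline consumes.
#'
#' @param cfg A [synth_config()]; the default is the scaled-down fixture
#'   configuration.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated tables, specs, grid levels,
#'   fused target size, and file paths.
#' @export
gen_end_to_end_fixture <- function(cfg = synth_config(n_drugs = 1170,
                                                      n_drug_assays = 2000,
                                                      n_nps = 24,
                                                      n_np_assays = 200),
                                   dir = tempfile("nanoptml_fixture_")) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  drug <- gen_drug_assays(cfg)
  np <- gen_np_assays(cfg)
  paths <- list(
    drug = file.path(dir, "drug_assays.csv"),
    np = file.path(dir, "np_assays.csv"),
    disc_drug = file.path(dir, "discretization_drug.yaml"),
    disc_np = file.path(dir, "discretization_np.yaml"),
    features = file.path(dir, "pt_features.yaml")
  )
  write_assay_table(drug, paths$drug)
  write_assay_table(np, paths$np)
  write_discretization_spec(default_discretization("drug"), paths$disc_drug)
  write_discretization_spec(default_discretization("np"), paths$disc_np)
  write_pt_feature_spec(default_pt_features(), paths$features)
  invisible(list(
    cfg = cfg,
    drug_table = drug,
    np_table = np,
    disc_drug = default_discretization("drug"),
    disc_np = default_discretization("np"),
    feature_spec = default_pt_features(),
    levels = levels_from_tables(drug, np),
    fused_target = 20000,
    paths = paths,
    dir = dir
  ))
}
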