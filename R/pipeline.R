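#' Run the reconstruct-curate-validate pipeline over a synthetic bundle
#'
#' Orchestrates the automatable stages — draft evaluation, structural
#' quality control, gap filling, biomass assembly, phenotype
#' validation, dynamic FBA — in that order, writing each stage's
#' tables before the next starts plus a machine-readable JSON summary.
#' Manual-curation steps (database cross-checks, literature review)
#' are represented by edited input files between stages, not
#' automated.
#'
#' @param config a named list (or path to a YAML file) with elements:
#'   \describe{
#'     \item{seed}{integer master seed for the synthetic inputs.}
#'     \item{out_dir}{output directory (created if missing).}
#'     \item{stages}{character subset of
#'       `c("draft_eval", "qc", "gapfill", "biomass", "phenotype",
#'       "dfba")`; default all.}
#'     \item{params}{optional overrides: `grid` (cutoff grid),
#'       `gam`, `dt`, `flip_p` (plate error rate), `epsilon`.}
#'   }
#'   Unknown top-level keys are rejected.
#' @return the summary list, invisibly; side effect: TSV/JSON files
#'   under `out_dir` and `summary.json` aggregating all stage metrics.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "out_dir", "stages", "params")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required", call. = FALSE)
  all_stages <- c("draft_eval", "qc", "gapfill", "biomass",
                  "phenotype", "dfba")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    stop("unknown stages: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  params <- config$params %||% list()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = seed, stages = stages)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  if ("draft_eval" %in% stages) {
    template_gprs <- list(r1 = "tA and tB", r2 = "tC", r3 = "tD or tE")
    reference <- list(r1 = c("q1", "q2"), r2 = "q3", r3 = c("q4"))
    hom <- gen_homology_table(seed, template_gprs, reference,
                              n_decoys = 40)
    grid <- params$grid %||% default_cutoff_grid()
    gtab <- grid_search(hom$hits, template_gprs, reference, grid = grid)
    tsv(gtab, "draft_eval_grid.tsv")
    summary$draft_eval <- list(
      n_grid_points = nrow(gtab),
      best_fn = min(gtab$fn_accumulative),
      best_fp = min(gtab$fp_accumulative))
  }

  toy <- gen_toy_network(seed, plant_dead_end = TRUE)
  if ("qc" %in% stages) {
    de <- find_dead_ends(toy$model)
    bal <- check_balances(toy$model)
    orph <- list_orphans(toy$model)
    cycle_toy <- gen_toy_network(seed, plant_energy_cycle = TRUE)
    leak <- energy_leak_check(
      cycle_toy$model, dissipation = CURRENCY_DISSIPATION["ATP"])
    tsv(de, "qc_dead_ends.tsv")
    tsv(bal$report, "qc_balances.tsv")
    summary$qc <- list(
      n_dead_ends = nrow(de),
      planted_dead_end_found = all(toy$truth$dead_ends %in% de$metabolite),
      balance_pass = bal$pass,
      n_orphans = length(orph$orphans),
      planted_energy_cycle_detected = !leak$pass)
  }

  if ("gapfill" %in% stages) {
    broken <- toy$model
    broken$reactions[["T_sub"]]$lower_bound <- 0
    broken$reactions[["T_sub"]]$upper_bound <- 0
    universal <- metabolic_model(
      id = "universal",
      compartments = toy$model$compartments,
      metabolites = toy$model$metabolites,
      reactions = c(
        list(reaction("U_T_sub", c(sub_e = -1, sub_c = 1))),
        lapply(1:3, function(i) {
          # useless candidates: consume biomass precursor
          reaction(sprintf("U_decoy%d", i), c(bm_c = -1, sub_c = 1))
        })))
    gf <- gapfill(broken, universal, target = "BIOMASS",
                  medium = c(EX_sub = 10),
                  epsilon = params$epsilon %||% 1e-3)
    summary$gapfill <- list(status = gf$status, added = gf$added,
                            cost = gf$cost)
  }

  if ("biomass" %in% stages) {
    prot <- gen_sequences(seed, "protein", length = 20000)
    gen <- gen_sequences(seed, "dna", length = 20000, gc_content = 0.65)
    aa <- amino_acid_coefficients(prot, protein_mass_fraction = 0.55)
    nt <- nucleotide_coefficients(gen, dna_fraction = 0.031,
                                  rna_fraction = 0.205)
    comp <- default_bof_composition(aa, nt)
    bof <- assemble_bof(normalize_bof_composition(comp),
                        gam = params$gam %||% 40)
    tsv(aa, "biomass_amino_acids.tsv")
    summary$biomass <- list(
      n_constituents = attr(bof, "n_constituents"),
      n_clusters = length(attr(bof, "clusters")))
  }

  if ("phenotype" %in% stages) {
    plate_model <- gen_plate_model(seed, n_substrates = 12,
                                   n_usable = 7)$model
    pl <- gen_phenotype_plate(plate_model, seed,
                              p = params$flip_p %||% 0.1)
    sim <- simulate_plate(plate_model, pl$plate,
                          base_medium = stats::setNames(numeric(0),
                                                        character(0)),
                          class_exchanges =
                            reactions_of_kind(plate_model, "exchange"))
    cm <- confusion_matrix(sim$experimental, sim$predicted)
    st <- confusion_stats(cm)
    tsv(sim, "phenotype_simulations.tsv")
    summary$phenotype <- c(cm, as.list(st$rounded))
  }

  if ("dfba" %in% stages) {
    mdl <- toy_chain_model(yield = 0.05)
    ser <- gen_kinetic_series(seed, v = 5, Y = 0.05, X0 = 0.01,
                              S0 = 20, sigma = 0.01)
    dt <- params$dt %||% 0.1
    kin <- calibrate(mdl, list(biomass = 0.01, substrates = c(EX_glc = 20)),
                     observations = data.frame(
                       time = ser$data$time, biomass = ser$data$biomass,
                       EX_glc = ser$data$substrate),
                     dt = dt)
    tr <- dfba_simulate(mdl, list(biomass = 0.01,
                                  substrates = c(EX_glc = 20)),
                        kin, dt = dt, t_end = max(ser$data$time))
    fs <- fit_statistics(tr, data.frame(time = ser$data$time,
                                        biomass = ser$data$biomass))
    tsv(tr, "dfba_trajectory.tsv")
    summary$dfba <- list(vmax_fitted = unname(kin[["EX_glc"]]),
                         r_squared = fs$r_squared,
                         log10_p = fs$log10_p)
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(summary)
}

#' A compact default biomass composition covering the nine clusters
#'
#' Amino acids and nucleotides come from the supplied composition
#' tables; the remaining clusters carry representative constituents
#' with literature-convention mass fractions of a Gram-negative
#' phototroph (cell wall 15%, carbohydrates 5%, cofactors 2%, pigments
#' 2%, minerals 1%, miscellaneous: the remainder). Intended for toys,
#' examples and the pipeline driver; organism work supplies real
#' tables.
#'
#' @param aa output of [amino_acid_coefficients()].
#' @param nt output of [nucleotide_coefficients()].
#' @return a compositions list for [assemble_bof()].
#' @export
default_bof_composition <- function(aa, nt) {
  aa_df <- data.frame(
    metabolite = paste0(tolower(aa$amino_acid), "__L_c"),
    coefficient = aa$coefficient, mw = aa$residue_mw,
    stringsAsFactors = FALSE)
  dna_df <- data.frame(
    metabolite = paste0("d", tolower(nt$dna$base), "tp_c"),
    coefficient = nt$dna$coefficient, mw = nt$dna$residue_mw,
    stringsAsFactors = FALSE)
  rna_df <- data.frame(
    metabolite = paste0(tolower(nt$rna$base), "tp_c"),
    coefficient = nt$rna$coefficient, mw = nt$rna$residue_mw,
    stringsAsFactors = FALSE)
  simple <- function(met, fraction, mw) {
    data.frame(metabolite = met, coefficient = 1000 * fraction / mw,
               mw = mw, stringsAsFactors = FALSE)
  }
  list(
    amino_acids = aa_df,
    DNA = dna_df,
    RNA = rna_df,
    cell_wall = simple("peptido_c", 0.15, 1000),
    carbohydrates = simple("glycogen_c", 0.05, 162.14),
    cofactors = simple("nad_c", 0.02, 663.43),
    pigments = simple("bchl_c", 0.02, 911.5),
    minerals = simple("k_c", 0.01, 39.1),
    miscellaneous = simple("misc_c", 0.014, 500))
}
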