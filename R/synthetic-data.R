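#' Seeded synthetic-data generators
#'
#' Every pipeline stage is exercised on generated inputs with known
#' ground truth: toy metabolic networks with hand-computable optima,
#' homology tables with planted orthologs and decoys, phenotype plates
#' with a controlled call-flip rate, kinetic batch time courses from
#' the closed-form exponential solution, and sequence sets of given
#' composition. Every generator derives an isolated RNG stream from
#' `(seed, label)`, so outputs are reproducible and adding a generator
#' never perturbs existing ones; the caller's RNG state is untouched.
#' Ground truth is always computed constructively from the generating
#' parameters, never by running the analysis modules under test.
#'
#' @name synthetic_data
NULL

# isolated, label-salted RNG stream; restores the caller's RNG state
with_gen_seed <- function(seed, label, code) {
  salt <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) * 7919L + salt) %% 2147483647L)
  force(code)
}

#' A minimal linear chain model: uptake, transport, conversion, biomass
#'
#' `EX_glc <-> glc_e`, `T: glc_e -> glc_c`, `R: glc_c -> yield x bm_c`,
#' `BIOMASS: bm_c ->`. With uptake bound u the optimal growth rate is
#' `u * yield`.
#'
#' @param yield biomass per substrate (default 0.5).
#' @param uptake default uptake bound on `EX_glc` (default 10).
#' @return a [metabolic_model()].
#' @export
toy_chain_model <- function(yield = 0.5, uptake = 10) {
  metabolic_model(
    id = "toy_chain",
    compartments = c(c = "cytoplasm", e = "extracellular"),
    metabolites = list(
      metabolite("glc_e", compartment = "e", formula = "C6H12O6",
                 charge = 0L),
      metabolite("glc_c", compartment = "c", formula = "C6H12O6",
                 charge = 0L),
      metabolite("bm_c", compartment = "c")),
    reactions = list(
      reaction("EX_glc", c(glc_e = -1), lower_bound = -uptake,
               upper_bound = 1000, kind = "exchange"),
      reaction("T_glc", c(glc_e = -1, glc_c = 1), gpr = "gT"),
      reaction("R_bm", stats::setNames(c(-1, yield), c("glc_c", "bm_c")),
               gpr = "gR"),
      reaction("BIOMASS", c(bm_c = -1), kind = "biomass")),
    objective = "BIOMASS")
}

#' Generate a parameterised toy network with constructive ground truth
#'
#' Template: substrate uptake -> transport -> a branch of conversion
#' routes with configurable yields -> biomass export. Options plant a
#' dead-end metabolite (produced, never consumed), a futile
#' ATP-generating cycle, and AND/OR GPR structure on the routes. The
#' ground-truth record (optimal growth rate, essential genes, dead
#' ends) is derived from the construction arithmetic, not from the
#' flux engine.
#'
#' @param seed integer master seed (controls id decoration only; truth
#'   values depend only on the size/yield parameters).
#' @param yields numeric vector of route yields (biomass per
#'   substrate), one conversion route each.
#' @param uptake uptake bound on the substrate exchange.
#' @param plant_dead_end add a terminal by-product metabolite.
#' @param plant_energy_cycle add an erroneous reversible duplicate of
#'   the ATP synthase-like reaction, creating a free-energy loop.
#' @param decorate_ids prefix metabolite/gene ids with a seed-derived
#'   tag (truth is unchanged).
#' @return list with `model` and `truth` (list: `mu_optimal`,
#'   `best_route`, `essential_genes`, `dead_ends`, `has_energy_cycle`).
#' @export
gen_toy_network <- function(seed = 1, yields = c(0.5, 0.8), uptake = 10,
                            plant_dead_end = FALSE,
                            plant_energy_cycle = FALSE,
                            decorate_ids = FALSE) {
  stopifnot(length(yields) >= 1, all(yields > 0), uptake >= 0)
  tag <- if (decorate_ids) {
    with_gen_seed(seed, "toy_network",
                  paste0(paste(sample(letters, 4), collapse = ""), "_"))
  } else ""
  p <- function(x) paste0(tag, x)

  mets <- list(
    metabolite(p("sub_e"), compartment = "e"),
    metabolite(p("sub_c"), compartment = "c"),
    metabolite(p("bm_c"), compartment = "c"))
  rxns <- list(
    reaction(p("EX_sub"), stats::setNames(-1, p("sub_e")),
             lower_bound = -uptake, upper_bound = 1000,
             kind = "exchange"),
    reaction(p("T_sub"),
             stats::setNames(c(-1, 1), c(p("sub_e"), p("sub_c"))),
             gpr = paste0(p("gT1"), " or ", p("gT2")),
             subsystem = "transport"))
  for (i in seq_along(yields)) {
    rxns[[length(rxns) + 1]] <- reaction(
      p(sprintf("R_route%d", i)),
      stats::setNames(c(-1, yields[i]), c(p("sub_c"), p("bm_c"))),
      gpr = paste0(p(sprintf("gR%da", i)), " and ",
                   p(sprintf("gR%db", i))),
      subsystem = "central")
  }
  rxns[[length(rxns) + 1]] <- reaction(
    p("BIOMASS"), stats::setNames(-1, p("bm_c")), kind = "biomass")

  dead_ends <- character(0)
  if (plant_dead_end) {
    mets[[length(mets) + 1]] <- metabolite(p("waste_c"),
                                           compartment = "c")
    # a terminal by-product branch: produced, never consumed; the
    # optimum never routes flux here, so planting it leaves the
    # network's growth arithmetic untouched
    rxns[[length(rxns) + 1]] <- reaction(
      p("D_waste"),
      stats::setNames(c(-1, 0.1), c(p("sub_c"), p("waste_c"))),
      subsystem = "central")
    dead_ends <- p("waste_c")
  }
  if (plant_energy_cycle) {
    mets <- c(mets, list(
      metabolite(p("atp_c"), compartment = "c"),
      metabolite(p("adp_c"), compartment = "c"),
      metabolite(p("pi_c"), compartment = "c"),
      metabolite(p("h_c"), compartment = "c"),
      metabolite(p("h2o_c"), compartment = "c")))
    # erroneously reversible duplicate of the ATP maintenance
    # hydrolysis: running it backwards regenerates ATP for free, so
    # together with any forward hydrolysis it forms an
    # ATP-from-nothing loop
    rxns[[length(rxns) + 1]] <- reaction(
      p("ATPM_dup"), stats::setNames(c(-1, -1, 1, 1, 1),
                                     c(p("atp_c"), p("h2o_c"),
                                       p("adp_c"), p("pi_c"), p("h_c"))),
      lower_bound = -1000, subsystem = "energy")
  }

  model <- metabolic_model(
    id = paste0("toy_", seed),
    compartments = c(c = "cytoplasm", e = "extracellular"),
    metabolites = mets, reactions = rxns, objective = p("BIOMASS"))

  best <- which.max(yields)
  truth <- list(
    mu_optimal = uptake * max(yields),
    best_route = p(sprintf("R_route%d", best)),
    # single-route genes are essential only when there is one route;
    # transport is OR (either gene suffices), so neither gT is essential
    essential_genes = if (length(yields) == 1) {
      c(p("gR1a"), p("gR1b"))
    } else character(0),
    dead_ends = dead_ends,
    has_energy_cycle = plant_energy_cycle)
  list(model = model, truth = truth)
}

#' Generate a homology hit table with planted orthologs and decoys
#'
#' Every gene of the curated reference receives exactly one planted hit
#' to a template gene of its reaction, with e-value at or below
#' `planted_e`, alignment length at or above `planted_len` and identity
#' at or above `planted_ident`. Decoy hits map decoy query genes to
#' random template genes with parameters strictly worse than the
#' planting thresholds (unless `decoys_above` asks for a number of
#' decoys that do pass, for cutoff-straddling tests).
#'
#' @param seed integer seed.
#' @param template_gprs named list, reaction id -> GPR rule over
#'   template genes.
#' @param reference named list, reaction id -> true target gene set.
#' @param n_decoys number of sub-threshold decoy hits.
#' @param decoys_above number of decoy hits planted above (passing)
#'   the thresholds, default 0.
#' @param planted_e,planted_len,planted_ident planting thresholds
#'   (defaults 1e-5, 100, 30 — the reconstruction's final cutoffs).
#' @return list with `hits` (data.frame in [read_hit_table()] layout),
#'   `planted` (the true-hit subset), `decoys_above_threshold`
#'   (character decoy query ids that pass the planting cutoffs).
#' @export
gen_homology_table <- function(seed, template_gprs, reference,
                               n_decoys = 50, decoys_above = 0,
                               planted_e = 1e-5, planted_len = 100,
                               planted_ident = 30) {
  with_gen_seed(seed, "homology_table", {
    rows <- list()
    for (r in names(reference)) {
      tg <- gpr_genes(parse_gpr(template_gprs[[r]]))
      for (g in reference[[r]]) {
        rows[[length(rows) + 1]] <- data.frame(
          query = g, subject = sample(tg, 1),
          identity_pct = planted_ident + stats::runif(1, 0, 40),
          alignment_length = as.integer(planted_len +
                                          sample(0:200, 1)),
          e_value = planted_e * 10^(-stats::runif(1, 0, 20)),
          query_coverage_pct = stats::runif(1, 80, 100),
          planted = TRUE, stringsAsFactors = FALSE)
      }
    }
    all_template <- unique(unlist(lapply(template_gprs, function(x) {
      gpr_genes(parse_gpr(x))
    })))
    mk_decoy <- function(i, above) {
      data.frame(
        query = sprintf("decoy%03d", i),
        subject = sample(all_template, 1),
        identity_pct = if (above) {
          planted_ident + stats::runif(1, 0, 30)
        } else planted_ident - stats::runif(1, 5, 15),
        alignment_length = as.integer(
          if (above) planted_len + sample(0:100, 1) else {
            max(10, planted_len - sample(20:60, 1))
          }),
        e_value = if (above) {
          planted_e * 10^(-stats::runif(1, 0, 10))
        } else planted_e * 10^stats::runif(1, 2, 6),
        query_coverage_pct = stats::runif(1, 30, 100),
        planted = FALSE, stringsAsFactors = FALSE)
    }
    decoys <- lapply(seq_len(n_decoys + decoys_above), function(i) {
      mk_decoy(i, above = i <= decoys_above)
    })
    hits <- do.call(rbind, c(rows, decoys))
    rownames(hits) <- NULL
    list(hits = hits[, setdiff(names(hits), "planted")],
         planted = hits[hits$planted, , drop = FALSE],
         decoys_above_threshold =
           unique(hits$query[!hits$planted &
                               hits$e_value <= planted_e &
                               hits$alignment_length >= planted_len &
                               hits$identity_pct >= planted_ident]))
  })
}

#' Generate a multi-substrate plate model
#'
#' A star-shaped network for phenotype-array tests: `n_substrates`
#' external substrates each get an exchange and a transport reaction,
#' and the first `n_usable` also a conversion route to the biomass
#' precursor. A substrate therefore supports growth iff it is usable —
#' ground truth by construction.
#'
#' @param seed integer seed (id decoration only).
#' @param n_substrates number of plated substrates.
#' @param n_usable how many of them can be catabolised (<=
#'   `n_substrates`).
#' @param yield biomass yield of the usable routes.
#' @return list with `model`, `usable` (exchange ids supporting
#'   growth) and `unusable`.
#' @export
gen_plate_model <- function(seed = 1, n_substrates = 12, n_usable = 7,
                            yield = 0.5) {
  stopifnot(n_usable <= n_substrates, n_substrates >= 1)
  mets <- list(metabolite("bm_c", compartment = "c"))
  rxns <- list(reaction("BIOMASS", c(bm_c = -1), kind = "biomass"))
  ex_ids <- sprintf("EX_sub%02d", seq_len(n_substrates))
  for (i in seq_len(n_substrates)) {
    e <- sprintf("sub%02d_e", i); cmet <- sprintf("sub%02d_c", i)
    mets <- c(mets, list(metabolite(e, compartment = "e"),
                         metabolite(cmet, compartment = "c")))
    rxns <- c(rxns, list(
      reaction(ex_ids[i], stats::setNames(-1, e), lower_bound = 0,
               upper_bound = 1000, kind = "exchange"),
      reaction(sprintf("T_sub%02d", i),
               stats::setNames(c(-1, 1), c(e, cmet)),
               gpr = sprintf("gT%02d", i))))
    if (i <= n_usable) {
      rxns <- c(rxns, list(reaction(
        sprintf("R_sub%02d", i),
        stats::setNames(c(-1, yield), c(cmet, "bm_c")),
        gpr = sprintf("gR%02d", i), subsystem = "catabolism")))
    }
  }
  model <- metabolic_model(
    id = sprintf("plate_toy_%d", seed),
    compartments = c(c = "cytoplasm", e = "extracellular"),
    metabolites = mets, reactions = rxns, objective = "BIOMASS")
  list(model = model,
       usable = ex_ids[seq_len(n_usable)],
       unusable = setdiff(ex_ids, ex_ids[seq_len(n_usable)]))
}

#' Generate a phenotype plate with a planted call-flip rate
#'
#' True growth calls are computed constructively by graph reachability
#' (can the substrate reach the biomass precursors through the
#' reaction bipartite graph, with the base medium's metabolites
#' available?), then flipped independently with probability `p` to
#' emulate experimental error. The flip log is recorded so
#' `truth XOR flips == emitted calls` can be audited.
#'
#' @param model a [metabolic_model()].
#' @param seed integer seed.
#' @param substrates exchange ids to plate (default: all exchanges).
#' @param base_mets metabolite ids always available (from the base
#'   medium), default none.
#' @param p call-flip probability (default 0).
#' @param n_wells number of plate wells; when larger than the number
#'   of substrates, wells resample substrates with replacement
#'   (replicate wells).
#' @return list with `plate` (data.frame `substrate`, `exchange`,
#'   `call`), `truth` (character true calls per well), `flips`
#'   (logical per well).
#' @export
gen_phenotype_plate <- function(model, seed, substrates = NULL,
                                base_mets = character(0), p = 0,
                                n_wells = NULL) {
  if (is.null(substrates)) {
    substrates <- reactions_of_kind(model, "exchange")
  }
  bm_rxn <- model$objective
  needed <- names(model$reactions[[bm_rxn]]$stoichiometry)
  needed <- needed[model$reactions[[bm_rxn]]$stoichiometry[needed] < 0]
  all_ex <- reactions_of_kind(model, "exchange")
  truth <- vapply(substrates, function(ex) {
    seed_met <- names(model$reactions[[ex]]$stoichiometry)
    reach <- reachable_metabolites(model, c(seed_met, base_mets),
                                   exclude = all_ex)
    if (all(needed %in% reach)) "growth" else "no_growth"
  }, character(1))
  with_gen_seed(seed, "phenotype_plate", {
    wells <- if (is.null(n_wells) || n_wells == length(substrates)) {
      substrates
    } else {
      sample(substrates, n_wells, replace = TRUE)
    }
    well_truth <- unname(truth[wells])
    flips <- stats::runif(length(wells)) < p
    calls <- ifelse(flips,
                    ifelse(well_truth == "growth", "no_growth", "growth"),
                    well_truth)
    list(plate = data.frame(substrate = wells,
                            exchange = wells,
                            call = unname(calls),
                            stringsAsFactors = FALSE),
         truth = well_truth, flips = unname(flips))
  })
}

# forward closure over the reaction bipartite graph: a reaction fires
# once all its substrates are available (reversible reactions in either
# direction); purely structural, no flux engine involved
reachable_metabolites <- function(model, start, exclude = character(0)) {
  avail <- unique(start)
  rxns <- model$reactions[setdiff(names(model$reactions), exclude)]
  repeat {
    added <- FALSE
    for (r in rxns) {
      st <- r$stoichiometry
      subs <- names(st)[st < 0]; prods <- names(st)[st > 0]
      fwd <- r$upper_bound > 0 && all(subs %in% avail) &&
        !all(prods %in% avail)
      rev <- r$lower_bound < 0 && all(prods %in% avail) &&
        !all(subs %in% avail)
      if (fwd) { avail <- unique(c(avail, prods)); added <- TRUE }
      if (rev) { avail <- unique(c(avail, subs)); added <- TRUE }
    }
    if (!added) break
  }
  avail
}

#' Generate a noisy kinetic batch time course from the closed form
#'
#' For constant specific uptake v and yield Y the batch ODEs
#' `dX/dt = mu X`, `dS/dt = -v X` with `mu = Y v` have the closed-form
#' solution `X(t) = X0 exp(mu t)`,
#' `S(t) = S0 - (v X0 / mu)(exp(mu t) - 1)`. Points are sampled in the
#' exponential phase only (up to substrate depletion) and Gaussian
#' noise of standard deviation `sigma` (relative) is added.
#'
#' @param seed integer seed.
#' @param mu specific growth rate (1/h); alternatively supply `v` and
#'   `Y` and `mu = Y * v` is used.
#' @param v specific uptake rate (mmol/gDW/h).
#' @param Y yield (gDW per mmol substrate).
#' @param X0 initial biomass (gDW/L).
#' @param S0 initial substrate (mM).
#' @param sigma relative Gaussian noise level (0 = noiseless).
#' @param n_points number of observation times.
#' @return list with `data` (data.frame `time`, `biomass`,
#'   `substrate`) and `truth` (the generating parameters and the
#'   depletion time).
#' @export
gen_kinetic_series <- function(seed, v, Y, X0, S0, sigma = 0,
                               n_points = 12, mu = Y * v) {
  stopifnot(v > 0, Y > 0, X0 > 0, S0 > 0, sigma >= 0, n_points >= 2)
  t_deplete <- log(1 + mu * S0 / (v * X0)) / mu
  times <- seq(0, 0.98 * t_deplete, length.out = n_points)
  X <- X0 * exp(mu * times)
  S <- S0 - (v * X0 / mu) * (exp(mu * times) - 1)
  with_gen_seed(seed, "kinetic_series", {
    Xn <- X * (1 + sigma * stats::rnorm(n_points))
    Sn <- pmax(S * (1 + sigma * stats::rnorm(n_points)), 0)
    list(data = data.frame(time = times, biomass = Xn, substrate = Sn),
         truth = list(v = v, Y = Y, mu = mu, X0 = X0, S0 = S0,
                      sigma = sigma, t_deplete = t_deplete))
  })
}

#' Generate random sequences of specified composition
#'
#' @param seed integer seed.
#' @param type `"protein"` or `"dna"`.
#' @param length total residue count (> 0).
#' @param frequencies named residue frequencies summing to 1 (protein;
#'   default uniform over the 20 amino acids).
#' @param gc_content for DNA: target G+C fraction (default 0.5; A/T
#'   and G/C split evenly).
#' @param n_seqs number of records the residues are split across.
#' @return a [Biostrings::AAStringSet] or [Biostrings::DNAStringSet].
#' @export
gen_sequences <- function(seed, type = c("protein", "dna"), length,
                          frequencies = NULL, gc_content = 0.5,
                          n_seqs = 1) {
  type <- match.arg(type)
  if (length <= 0) stop("sequence length must be positive", call. = FALSE)
  if (type == "protein") {
    if (is.null(frequencies)) {
      frequencies <- stats::setNames(rep(1 / 20, 20), names(AA_RESIDUE_MW))
    }
    stopifnot(abs(sum(frequencies) - 1) < 1e-9)
    letters_pool <- names(frequencies)
    probs <- as.numeric(frequencies)
  } else {
    letters_pool <- c("A", "C", "G", "T")
    probs <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
               (1 - gc_content) / 2)
  }
  with_gen_seed(seed, paste0("sequences_", type), {
    chars <- sample(letters_pool, length, replace = TRUE, prob = probs)
    breaks <- sort(rep(seq_len(n_seqs), length.out = length))
    seqs <- vapply(split(chars, breaks), paste, character(1),
                   collapse = "")
    names(seqs) <- sprintf("synthetic_%03d", seq_along(seqs))
    if (type == "protein") {
      Biostrings::AAStringSet(seqs)
    } else {
      Biostrings::DNAStringSet(seqs)
    }
  })
}
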