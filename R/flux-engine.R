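#' Flux balance analysis
#'
#' Solves the linear program `max (or min) v_objective` subject to
#' steady-state mass balance `S v = 0` and flux bounds `lb <= v <= ub`,
#' with exchange bounds overridden by `medium`. Units are
#' mmol/gDW/h; the optimal biomass flux is the specific growth rate in
#' 1/h.
#'
#' Uptake follows the convention that exchange reactions are written as
#' `met_e <-> (environment)`, so uptake is a negative exchange flux: a
#' medium entry of 10 sets the exchange lower bound to -10. Exchange
#' reactions absent from a non-`NULL` medium get their uptake closed
#' (lower bound 0); secretion stays as bounded in the model.
#'
#' @param model a [metabolic_model()].
#' @param medium named numeric vector, exchange reaction id ->
#'   non-negative maximal uptake (mmol/gDW/h), or `NULL` to use the
#'   model's own bounds unchanged.
#' @param objective objective reaction id; defaults to the model
#'   objective.
#' @param sense `"max"` or `"min"`.
#' @param zero_tol fluxes below this magnitude are clamped to zero in
#'   the reported vector (default 1e-9).
#' @return a `flux_solution`: list with `status` (`"optimal"` or
#'   `"infeasible"`), `objective` (optimal value; `NA` if infeasible)
#'   and `fluxes` (named vector, one optimal vertex).
#' @examples
#' m <- toy_chain_model()
#' fba(m, medium = c(EX_glc = 10))$objective
#' @export
fba <- function(model, medium = NULL, objective = model$objective,
                sense = c("max", "min"), zero_tol = 1e-9) {
  sense <- match.arg(sense)
  if (is.null(objective) || !objective %in% names(model$reactions)) {
    stop("objective reaction not found: ",
         if (is.null(objective)) "<NULL>" else objective, call. = FALSE)
  }
  model <- apply_medium(model, medium)
  rxn_ids <- names(model$reactions)
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- vapply(model$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(model$reactions, `[[`, numeric(1), "upper_bound")
  obj <- as.numeric(rxn_ids == objective)
  sol <- solve_lp(obj, Aeq = S, beq = rep(0, nrow(S)), lb = lb, ub = ub,
                  maximize = (sense == "max"))
  fluxes <- sol$x
  names(fluxes) <- rxn_ids
  if (sol$status == "optimal") fluxes[abs(fluxes) < zero_tol] <- 0
  structure(list(status = sol$status,
                 objective = if (sol$status == "optimal") {
                   sol$objective
                 } else NA_real_,
                 fluxes = fluxes),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status:", x$status,
      " objective:", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Apply a medium specification to a model
#'
#' @inheritParams fba
#' @return the model with exchange lower bounds overridden: listed
#'   exchanges opened to `-uptake`, unlisted exchanges closed (lower
#'   bound 0). A `NULL` medium leaves the model untouched.
#' @export
apply_medium <- function(model, medium) {
  if (is.null(medium)) return(model)
  ex_ids <- reactions_of_kind(model, "exchange")
  bad <- setdiff(names(medium), ex_ids)
  if (length(bad) > 0) {
    stop("medium references non-exchange reactions: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(medium < 0)) {
    stop("medium uptake values must be non-negative magnitudes",
         call. = FALSE)
  }
  for (rid in ex_ids) {
    model$reactions[[rid]]$lower_bound <-
      if (rid %in% names(medium)) -unname(medium[[rid]]) else 0
    model$reactions[[rid]]$upper_bound <-
      max(model$reactions[[rid]]$upper_bound, 0)
  }
  model
}

#' Threshold above which an optimal biomass flux counts as growth
#' (1/h). Qualitative growth calls reduce FBA results to
#' growth/no-growth at this cutoff.
#' @export
GROWTH_THRESHOLD <- 1e-6

#' Single-gene deletion scan
#'
#' For each gene, every GPR rule is evaluated with that gene inactive;
#' reactions whose rule turns false are blocked (bounds 0, 0) and the
#' FBA is re-run. A gene is essential when the knockout growth rate
#' falls below `essentiality_fraction` of the wildtype rate.
#'
#' @inheritParams fba
#' @param genes gene ids to test (default: all model genes).
#' @param essentiality_fraction knockout/wildtype growth ratio below
#'   which a gene is called essential (default 0.05).
#' @return data.frame with columns `gene`, `mu_knockout`,
#'   `mu_wildtype`, `essential`.
#' @export
single_gene_deletion <- function(model, medium = NULL, genes = model$genes,
                                 essentiality_fraction = 0.05) {
  if (!any(vapply(model$reactions, function(r) !is.null(r$gpr_ast),
                  logical(1)))) {
    stop("model has no GPR rules; nothing to delete", call. = FALSE)
  }
  model <- apply_medium(model, medium)
  wt <- fba(model)
  mu_wt <- if (wt$status == "optimal") wt$objective else 0
  res <- lapply(genes, function(g) {
    ko <- model
    blocked <- FALSE
    for (rid in names(ko$reactions)) {
      ast <- ko$reactions[[rid]]$gpr_ast
      if (is.null(ast)) next
      if (!eval_gpr(ast, stats::setNames(FALSE, g), default = TRUE)) {
        ko$reactions[[rid]]$lower_bound <- 0
        ko$reactions[[rid]]$upper_bound <- 0
        blocked <- TRUE
      }
    }
    mu_ko <- if (!blocked) {
      mu_wt
    } else {
      s <- fba(ko)
      if (s$status == "optimal") s$objective else 0
    }
    data.frame(gene = g, mu_knockout = mu_ko, mu_wildtype = mu_wt,
               essential = mu_ko < essentiality_fraction * mu_wt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Producibility (sink) test for a metabolite
#'
#' Temporarily adds a sink reaction `met -> (nothing)` and maximizes its
#' flux under the given medium; the metabolite is producible when the
#' maximal sink flux exceeds `threshold`. The input model is not
#' modified.
#'
#' @inheritParams fba
#' @param met_id metabolite id to test.
#' @param threshold producibility cutoff on the maximal sink flux
#'   (default 1e-6 mmol/gDW/h).
#' @return list with `producible` (logical) and `max_flux`.
#' @export
sink_test <- function(model, met_id, medium = NULL, threshold = 1e-6) {
  if (!met_id %in% names(model$metabolites)) {
    stop("unknown metabolite: ", met_id, call. = FALSE)
  }
  sink_id <- paste0("SK_gemcurator_", met_id)
  tmp <- add_reaction(model, reaction(
    id = sink_id, stoichiometry = stats::setNames(-1, met_id),
    lower_bound = 0, upper_bound = GLOBAL_FLUX_BOUND, kind = "sink"))
  sol <- fba(tmp, medium = medium, objective = sink_id, sense = "max")
  mx <- if (sol$status == "optimal") sol$objective else 0
  list(producible = mx > threshold, max_flux = mx)
}

#' Default currency-metabolite dissipation stoichiometries
#'
#' ATP hydrolysis and NAD(P)H oxidation with standard cytosolic
#' metabolite ids, used by [energy_leak_check()].
#' @export
CURRENCY_DISSIPATION <- list(
  ATP = c(atp_c = -1, h2o_c = -1, adp_c = 1, pi_c = 1, h_c = 1),
  NADH = c(nadh_c = -1, nad_c = 1, h_c = 1),
  NADPH = c(nadph_c = -1, nadp_c = 1, h_c = 1))

#' Energy-leak (erroneous free-energy generation) check
#'
#' Closes the uptake of every exchange reaction, then adds in turn a
#' dissipation reaction for each currency carrier (ATP hydrolysis,
#' NADH and NADPH oxidation) and maximizes its flux. With no nutrient
#' entering, any positive dissipation flux can only come from a
#' thermodynamically infeasible internal cycle; the participating
#' reactions (the support of the flux vector) are reported. The model
#' passes when all three maxima are zero. The input medium is
#' irrelevant: exchanges are force-closed regardless.
#'
#' @param model a [metabolic_model()].
#' @param dissipation named list of dissipation stoichiometries to test
#'   (default ATP, NADH, NADPH with standard cytosolic ids). Entries
#'   whose metabolites are absent from the model are skipped with a
#'   warning.
#' @param leak_tol flux above which a dissipation maximum counts as a
#'   leak (default 1e-6).
#' @return list with `pass` (TRUE iff no leak found) and `report`, a
#'   list per currency with `max_flux`, `leak`, and `cycle` (reaction
#'   ids with nonzero flux in the leaking solution).
#' @export
energy_leak_check <- function(model, dissipation = CURRENCY_DISSIPATION,
                              leak_tol = 1e-6) {
  for (rid in reactions_of_kind(model, "exchange")) {
    model$reactions[[rid]]$lower_bound <-
      max(model$reactions[[rid]]$lower_bound, 0)
  }
  report <- list()
  for (nm in names(dissipation)) {
    st <- dissipation[[nm]]
    missing <- setdiff(names(st), names(model$metabolites))
    if (length(missing) > 0) {
      warning("energy_leak_check: skipping ", nm,
              " (metabolites not in model: ",
              paste(missing, collapse = ", "), ")")
      next
    }
    diss_id <- paste0("DM_gemcurator_", nm)
    tmp <- add_reaction(model, reaction(
      id = diss_id, stoichiometry = st, lower_bound = 0,
      upper_bound = GLOBAL_FLUX_BOUND, kind = "demand"))
    sol <- fba(tmp, objective = diss_id, sense = "max")
    mx <- if (sol$status == "optimal") sol$objective else 0
    leak <- mx > leak_tol
    cycle <- if (leak) {
      v <- sol$fluxes
      setdiff(names(v)[abs(v) > 1e-9], diss_id)
    } else character(0)
    report[[nm]] <- list(max_flux = mx, leak = leak, cycle = cycle)
  }
  leaks <- vapply(report, `[[`, logical(1), "leak")
  list(pass = !any(leaks), report = report)
}
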