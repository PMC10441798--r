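#' Minimal-addition gap filling
#'
#' Makes a target (the biomass reaction, any other reaction, or a
#' metabolite wrapped in a temporary sink) carry flux of at least
#' `epsilon` by importing the cheapest set of reactions from a
#' universal database. Formulated as a mixed-integer program: one
#' binary y per candidate reaction, big-M coupling
#' `lb_i * y_i <= v_i <= ub_i * y_i`, objective `min sum(w_i * y_i)`
#' subject to the augmented network supporting target flux >= epsilon.
#' Solved by depth-first branch-and-bound over the LP relaxation. Ties
#' among equal-cost solutions are broken toward the lexicographically
#' smallest set of candidate reaction ids, for reproducibility.
#'
#' The returned set is re-validated by a plain FBA on the augmented
#' model before being reported (the post-condition is enforced in
#' code).
#'
#' @param model a [metabolic_model()].
#' @param universal a `metabolic_model` acting as the reaction
#'   database; candidate reactions are those whose id is not already in
#'   `model`. Metabolites referenced only by the universal database are
#'   carried along.
#' @param target a reaction id (flux forced >= epsilon) or a metabolite
#'   id (a temporary sink is added and forced).
#' @param medium medium specification (see [fba()]).
#' @param weights named non-negative costs per universal reaction id;
#'   unlisted candidates cost 1.
#' @param epsilon minimal target flux (default 1e-3 mmol/gDW/h).
#' @return a `gapfill_result`: list with `status` (`"optimal"`,
#'   `"already_feasible"` or `"infeasible"`), `added` (sorted candidate
#'   reaction ids), `cost`, `target_flux` achieved on the augmented
#'   model, and `target`.
#' @export
gapfill <- function(model, universal, target, medium = NULL,
                    weights = NULL, epsilon = 1e-3) {
  prep <- gapfill_prepare(model, universal, target, medium)
  cand <- prep$candidates
  w <- rep(1, length(cand))
  names(w) <- cand
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be >= 0", call. = FALSE)
    hit <- intersect(names(weights), cand)
    w[hit] <- weights[hit]
  }
  # already feasible without additions?
  base_flux <- gapfill_eval(prep, character(0))
  if (!is.na(base_flux) && base_flux >= epsilon - 1e-9) {
    return(structure(list(status = "already_feasible",
                          added = character(0), cost = 0,
                          target_flux = base_flux, target = target),
                     class = "gapfill_result"))
  }
  sol <- milp_min_additions(prep, w, epsilon)
  if (is.null(sol)) {
    return(structure(list(status = "infeasible", added = character(0),
                          cost = NA_real_, target_flux = NA_real_,
                          target = target),
                     class = "gapfill_result"))
  }
  added <- sol$added
  # post-condition: plain FBA on the augmented model reaches the target
  flux <- gapfill_eval(prep, added)
  if (is.na(flux) || flux < epsilon - 1e-6) {
    stop("internal error: gap-fill set fails FBA re-validation for ",
         target, call. = FALSE)
  }
  structure(list(status = "optimal", added = sort(added),
                 cost = sum(w[added]), target_flux = flux,
                 target = target),
            class = "gapfill_result")
}

#' @export
print.gapfill_result <- function(x, ...) {
  cat("<gapfill_result>", x$status, "target:", x$target, "\n")
  if (length(x$added) > 0) {
    cat("  added (cost ", x$cost, "): ",
        paste(x$added, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Build the augmented model (all candidates present) plus bookkeeping.
gapfill_prepare <- function(model, universal, target, medium) {
  cand <- setdiff(names(universal$reactions), names(model$reactions))
  aug <- model
  # carry over universal metabolites missing from the model
  for (mid in names(universal$metabolites)) {
    if (!mid %in% names(aug$metabolites)) {
      m <- universal$metabolites[[mid]]
      if (!m$compartment %in% names(aug$compartments)) {
        aug$compartments[[m$compartment]] <- m$compartment
      }
      aug$metabolites[[mid]] <- m
    }
  }
  for (rid in cand) {
    r <- universal$reactions[[rid]]
    r$gpr <- ""          # no gene evidence travels with a gap-fill
    r$gpr_ast <- NULL
    aug$reactions[[rid]] <- r
    aug$reactions[[rid]]$kind <- infer_reaction_kind(aug, rid)
  }
  if (target %in% names(aug$reactions)) {
    target_rxn <- target
  } else if (target %in% names(aug$metabolites)) {
    target_rxn <- paste0("SK_gapfill_", target)
    aug <- add_reaction(aug, reaction(
      id = target_rxn, stoichiometry = stats::setNames(-1, target),
      lower_bound = 0, upper_bound = GLOBAL_FLUX_BOUND, kind = "sink"))
  } else {
    stop("gap-fill target not resolvable: ", target, call. = FALSE)
  }
  aug <- apply_medium(aug, medium)
  list(aug = aug, candidates = sort(cand), target_rxn = target_rxn)
}

# Max target flux with only `added` candidates open; NA if infeasible.
gapfill_eval <- function(prep, added) {
  m <- prep$aug
  for (rid in setdiff(prep$candidates, added)) {
    m$reactions[[rid]]$lower_bound <- 0
    m$reactions[[rid]]$upper_bound <- 0
  }
  sol <- fba(m, medium = NULL, objective = prep$target_rxn, sense = "max")
  if (sol$status == "optimal") sol$objective else NA_real_
}

# Branch-and-bound MILP: min sum w_i y_i s.t. augmented network supports
# target flux >= epsilon; y binary per candidate. LP relaxation uses
# big-M coupling lb_i y_i <= v_i <= ub_i y_i with y in [0,1].
milp_min_additions <- function(prep, w, epsilon) {
  aug <- prep$aug
  cand <- prep$candidates
  rxn_ids <- names(aug$reactions)
  n <- length(rxn_ids)
  k <- length(cand)
  S <- as.matrix(stoichiometric_matrix(aug))
  lb <- vapply(aug$reactions, `[[`, numeric(1), "lower_bound")
  ub <- vapply(aug$reactions, `[[`, numeric(1), "upper_bound")
  lb <- pmax(lb, -GLOBAL_FLUX_BOUND); ub <- pmin(ub, GLOBAL_FLUX_BOUND)
  ti <- match(prep$target_rxn, rxn_ids)
  lb[ti] <- max(lb[ti], epsilon)   # force the target
  ci <- match(cand, rxn_ids)

  # variables: v (n fluxes), y (k indicators)
  obj <- c(rep(0, n), unname(w[cand]))
  Aeq <- cbind(S, matrix(0, nrow(S), k))
  beq <- rep(0, nrow(S))
  # v_i - ub_i y_i <= 0  and  -v_i + lb_i y_i <= 0
  Aup <- matrix(0, k, n + k); Alo <- matrix(0, k, n + k)
  for (j in seq_len(k)) {
    Aup[j, ci[j]] <- 1;  Aup[j, n + j] <- -ub[ci[j]]
    Alo[j, ci[j]] <- -1; Alo[j, n + j] <- lb[ci[j]]
  }
  Aineq <- rbind(Aup, Alo)
  bineq <- rep(0, 2 * k)

  tol <- 1e-6
  # integrality tolerance must be far below epsilon / big-M: the LP
  # relaxation can open a candidate at y = epsilon/1000 to satisfy the
  # target, and such a y must branch, not round to zero
  int_tol <- 1e-8
  yw <- obj[(n + 1):(n + k)]
  # depth-first branch-and-bound minimizing ycost'y over the binaries,
  # optionally under extra linear rows Ay y <= by; returns the optimal
  # value or Inf when infeasible
  bb_min <- function(ycost, ylb, yub, Ay = NULL, by = NULL) {
    A2 <- Aineq; b2 <- bineq
    if (!is.null(Ay)) {
      A2 <- rbind(A2, cbind(matrix(0, nrow(Ay), n), Ay))
      b2 <- c(b2, by)
    }
    cc <- c(rep(0, n), ycost)
    best <- Inf
    rec <- function(ylb, yub) {
      sol <- solve_lp(cc, Aeq = Aeq, beq = beq, Aineq = A2,
                      bineq = b2, lb = c(lb, ylb), ub = c(ub, yub),
                      maximize = FALSE)
      if (sol$status != "optimal") return(invisible(NULL))
      if (sol$objective >= best - tol) return(invisible(NULL))
      y <- sol$x[(n + 1):(n + k)]
      frac <- which(y > int_tol & y < 1 - int_tol)
      if (length(frac) == 0) {
        best <<- min(best, sum(ycost * (y > 0.5)))
        return(invisible(NULL))
      }
      j <- frac[1]                     # id-ordered branching
      u0 <- yub; u0[j] <- 0
      rec(ylb, u0)                     # explore y_j = 0 first
      l1 <- ylb; l1[j] <- 1
      rec(l1, yub)
      invisible(NULL)
    }
    rec(ylb, yub)
    best
  }
  free0 <- rep(0, k); free1 <- rep(1, k)
  c_star <- bb_min(yw, free0, free1)
  if (!is.finite(c_star)) return(NULL)
  # secondary objective: fewest additions among optimal-cost solutions
  # (rules out zero-weight free riders), then lexicographic tie-break:
  # include the smallest candidate ids an optimal solution can carry
  cost_row <- matrix(yw, 1)
  k_star <- bb_min(rep(1, k), free0, free1,
                   Ay = cost_row, by = c_star + tol)
  Ay <- rbind(cost_row, rep(1, k))
  by <- c(c_star + tol, k_star + tol)
  ylb <- free0; yub <- free1
  for (j in seq_len(k)) {
    l1 <- ylb; l1[j] <- 1
    if (is.finite(bb_min(rep(0, k), l1, yub, Ay = Ay, by = by))) {
      ylb <- l1
    } else {
      yub[j] <- 0
    }
  }
  list(added = cand[ylb == 1], cost = sum(yw * ylb))
}

#' Iterative per-condition gap filling
#'
#' Processes growth conditions in the given order; the reactions
#' accepted for one condition become part of the working model for all
#' later conditions, so shared repairs are added once. A condition
#' whose gap-fill is infeasible is recorded and iteration continues.
#'
#' @inheritParams gapfill
#' @param conditions list of conditions, each a list with elements
#'   `medium` and `target` (and optionally `name`).
#' @return list with `per_condition` (a `gapfill_result` per condition,
#'   named), `union` (all reaction ids added across conditions),
#'   `provenance` (data.frame `reaction`, `condition` recording which
#'   conditions required each addition), and `model` (the working model
#'   with all additions applied; additions carry no GPR and are marked
#'   orphan).
#' @export
iterative_condition_gapfill <- function(model, universal, conditions,
                                        weights = NULL, epsilon = 1e-3) {
  stopifnot(length(conditions) >= 1)
  nms <- vapply(seq_along(conditions), function(i) {
    conditions[[i]]$name %||% paste0("condition_", i)
  }, character(1))
  working <- model
  per <- list()
  prov_rxn <- character(0); prov_cond <- character(0)
  for (i in seq_along(conditions)) {
    cond <- conditions[[i]]
    res <- gapfill(working, universal, target = cond$target,
                   medium = cond$medium, weights = weights,
                   epsilon = epsilon)
    per[[nms[i]]] <- res
    if (res$status == "optimal" && length(res$added) > 0) {
      for (rid in res$added) {
        r <- universal$reactions[[rid]]
        r$gpr <- ""; r$gpr_ast <- NULL
        for (mid in setdiff(names(r$stoichiometry),
                            names(working$metabolites))) {
          m <- universal$metabolites[[mid]]
          if (!m$compartment %in% names(working$compartments)) {
            working$compartments[[m$compartment]] <- m$compartment
          }
          working$metabolites[[mid]] <- m
        }
        working <- add_reaction(working, r)
      }
    }
    # provenance: which accepted reactions this condition relies on
    if (res$status %in% c("optimal", "already_feasible")) {
      used <- res$added
      prov_rxn <- c(prov_rxn, used)
      prov_cond <- c(prov_cond, rep(nms[i], length(used)))
      # earlier additions this condition also needed: re-check by
      # removing each earlier addition and testing feasibility
      earlier <- setdiff(unique(prov_rxn), res$added)
      for (rid in earlier) {
        probe <- working
        probe$reactions[[rid]]$lower_bound <- 0
        probe$reactions[[rid]]$upper_bound <- 0
        probe <- apply_medium(probe, cond$medium)
        tgt <- cond$target
        if (!tgt %in% names(probe$reactions)) {
          probe <- add_reaction(probe, reaction(
            id = paste0("SK_gapfill_", tgt),
            stoichiometry = stats::setNames(-1, tgt),
            lower_bound = 0, upper_bound = GLOBAL_FLUX_BOUND,
            kind = "sink"))
          tgt <- paste0("SK_gapfill_", tgt)
        }
        s <- fba(probe, objective = tgt, sense = "max")
        if (s$status != "optimal" || s$objective < epsilon - 1e-9) {
          prov_rxn <- c(prov_rxn, rid)
          prov_cond <- c(prov_cond, nms[i])
        }
      }
    }
  }
  provenance <- unique(data.frame(reaction = prov_rxn,
                                  condition = prov_cond,
                                  stringsAsFactors = FALSE))
  provenance <- provenance[order(provenance$reaction,
                                 provenance$condition), , drop = FALSE]
  rownames(provenance) <- NULL
  list(per_condition = per,
       union = sort(unique(unlist(lapply(per, `[[`, "added")))),
       provenance = provenance,
       model = working)
}
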