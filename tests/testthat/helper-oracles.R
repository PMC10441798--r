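# Independent brute-force oracles; deliberately naive and separate from
# the implementations they check.

# LP oracle: enumerate all basic points of {S v = 0, lb <= v <= ub}
# by intersecting every full-rank subset of the constraint rows, keep
# the feasible ones, and take the best objective. Exponential — only
# for networks with <= 6 reactions.
vertex_enumeration_optimum <- function(S, lb, ub, obj, maximize = TRUE) {
  n <- length(obj)
  rows <- list()
  for (i in seq_len(nrow(S))) rows[[length(rows) + 1]] <- list(a = S[i, ], b = 0)
  for (i in seq_len(n)) {
    e <- numeric(n); e[i] <- 1
    rows[[length(rows) + 1]] <- list(a = e, b = lb[i])
    rows[[length(rows) + 1]] <- list(a = e, b = ub[i])
  }
  best <- if (maximize) -Inf else Inf
  cmb <- utils::combn(length(rows), n)
  for (k in seq_len(ncol(cmb))) {
    A <- t(vapply(rows[cmb[, k]], `[[`, numeric(n), "a"))
    bb <- vapply(rows[cmb[, k]], `[[`, numeric(1), "b")
    if (abs(det(A)) < 1e-9) next
    x <- solve(A, bb)
    if (max(abs(S %*% x)) > 1e-7) next
    if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
    val <- sum(obj * x)
    best <- if (maximize) max(best, val) else min(best, val)
  }
  best
}

fba_oracle <- function(model, medium = NULL, objective = model$objective) {
  model <- apply_medium(model, medium)
  S <- as.matrix(stoichiometric_matrix(model))
  lb <- pmax(vapply(model$reactions, `[[`, numeric(1), "lower_bound"), -1000)
  ub <- pmin(vapply(model$reactions, `[[`, numeric(1), "upper_bound"), 1000)
  obj <- as.numeric(names(model$reactions) == objective)
  vertex_enumeration_optimum(S, lb, ub, obj)
}

# dead-end oracle: explicit producer/consumer set enumeration on the
# metabolite-reaction bipartite graph
dead_end_oracle <- function(model) {
  out <- list()
  for (m in names(model$metabolites)) {
    touch <- 0L; prod <- FALSE; cons <- FALSE
    for (r in model$reactions) {
      co <- r$stoichiometry[m]
      if (is.na(co)) next
      touch <- touch + 1L
      rev <- r$lower_bound < 0 && r$upper_bound > 0
      if (co > 0 || rev) prod <- TRUE
      if (co < 0 || rev) cons <- TRUE
    }
    cls <- if (touch == 0L) NA_character_
      else if (touch == 1L) "single_reaction"
      else if (!prod) "substrate_only"
      else if (!cons) "product_only"
      else NA_character_
    if (!is.na(cls)) out[[m]] <- cls
  }
  df <- data.frame(
    metabolite = if (length(out)) names(out) else character(0),
    class = if (length(out)) unlist(out, use.names = FALSE) else character(0),
    stringsAsFactors = FALSE)
  df[order(df$metabolite), , drop = FALSE]
}

# gap-fill oracle: test subsets by increasing (cost, lexicographic)
# order and return the first whose augmented model reaches the target;
# feasibility judged by a plain FBA, not the MILP under test
gapfill_oracle <- function(model, universal, target, medium,
                           weights = NULL, epsilon = 1e-3) {
  cand <- sort(setdiff(names(universal$reactions),
                       names(model$reactions)))
  w <- stats::setNames(rep(1, length(cand)), cand)
  if (!is.null(weights)) {
    hit <- intersect(names(weights), cand)
    w[hit] <- weights[hit]
  }
  feasible <- function(subset) {
    aug <- model
    for (mid in setdiff(names(universal$metabolites),
                        names(aug$metabolites))) {
      mm <- universal$metabolites[[mid]]
      if (!mm$compartment %in% names(aug$compartments)) {
        aug$compartments[[mm$compartment]] <- mm$compartment
      }
      aug$metabolites[[mid]] <- mm
    }
    for (rid in subset) {
      r <- universal$reactions[[rid]]
      r$gpr <- ""; r$gpr_ast <- NULL
      aug <- add_reaction(aug, r)
    }
    tgt <- target
    if (!tgt %in% names(aug$reactions)) {
      aug <- add_reaction(aug, reaction(
        id = "SK_oracle", stoichiometry = stats::setNames(-1, tgt),
        lower_bound = 0, upper_bound = 1000, kind = "sink"))
      tgt <- "SK_oracle"
    }
    sol <- fba(aug, medium = medium, objective = tgt, sense = "max")
    sol$status == "optimal" && sol$objective >= epsilon - 1e-9
  }
  subsets <- list(character(0))
  for (k in seq_along(cand)) {
    subsets <- c(subsets, utils::combn(cand, k, simplify = FALSE))
  }
  costs <- vapply(subsets, function(s) sum(w[s]), numeric(1))
  ord <- order(costs, vapply(subsets, paste, character(1),
                             collapse = "|"))
  for (i in ord) {
    if (feasible(subsets[[i]])) {
      return(list(added = subsets[[i]], cost = costs[i]))
    }
  }
  NULL
}

# direct-formula MCC for the exhaustive symmetry checks
mcc_formula <- function(tp, tn, fp, fn) {
  den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / den
}

# random small networks for property tests: a loose chain with random
# extra reactions, some reversible
random_small_model <- function(seed, n_extra = 16) {
  set.seed(seed)
  n_met <- sample(6:10, 1)
  met_ids <- sprintf("m%02d_c", seq_len(n_met))
  mets <- lapply(met_ids, metabolite, compartment = "c")
  rxns <- list()
  for (j in seq_len(n_extra)) {
    k <- sample(2:3, 1)
    who <- sample(met_ids, k)
    co <- stats::setNames(c(-1, rep(1, k - 1)), who)
    lb <- if (stats::runif(1) < 0.3) -1000 else 0
    rxns[[j]] <- reaction(sprintf("r%02d", j), co, lower_bound = lb)
  }
  metabolic_model(sprintf("rand%d", seed),
                  compartments = c(c = "cytoplasm", e = "extracellular"),
                  metabolites = mets, reactions = rxns)
}
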