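#' Parse a chemical formula in Hill notation
#'
#' @param formula string such as `"C6H12O6"` or `"C10H12N5O13P3"`.
#' @return named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  if (is.na(formula) || !nzchar(formula)) {
    stop("cannot parse empty formula", call. = FALSE)
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(toks)) != nchar(formula)) {
    stop("formula parse error: '", formula, "'", call. = FALSE)
  }
  elems <- sub("[0-9]*$", "", toks)
  counts <- as.integer(ifelse(grepl("[0-9]+$", toks),
                              sub("^[A-Za-z]+", "", toks), "1"))
  out <- tapply(counts, elems, sum)
  stats::setNames(as.integer(out), names(out))
}

#' Elemental and charge balance report
#'
#' For every reaction, sums stoichiometric coefficient times element
#' count (and times charge) over all participating metabolites;
#' a balanced reaction has all element sums and the charge sum equal
#' to zero. Boundary pseudo-reactions (exchange, sink, demand, biomass)
#' are exempt — the biomass objective in particular is not elementally
#' balanced by design. Reactions touching any metabolite without a
#' formula are reported with status `"unknown"` rather than failed.
#' Charge balance is computed independently of the hydrogen count;
#' both are reported.
#'
#' @param model a [metabolic_model()].
#' @return list with `pass` (TRUE iff no checked reaction is
#'   unbalanced) and `report`, a data.frame with one row per checked
#'   reaction: `reaction`, `status` (`"balanced"`, `"unbalanced"`,
#'   `"unknown"`, `"exempt"`), `imbalance` (compact string of nonzero
#'   element/charge sums), and `net_charge`.
#' @export
check_balances <- function(model) {
  rows <- lapply(model$reactions, function(r) {
    if (r$kind %in% c("exchange", "sink", "demand", "biomass")) {
      return(data.frame(reaction = r$id, status = "exempt",
                        imbalance = "", net_charge = NA_real_,
                        stringsAsFactors = FALSE))
    }
    mets <- names(r$stoichiometry)
    formulas <- vapply(mets, function(m) {
      model$metabolites[[m]]$formula
    }, character(1))
    if (any(is.na(formulas))) {
      return(data.frame(reaction = r$id, status = "unknown",
                        imbalance = "", net_charge = NA_real_,
                        stringsAsFactors = FALSE))
    }
    net <- numeric(0)
    for (k in seq_along(mets)) {
      cnt <- parse_formula(formulas[k])
      for (e in names(cnt)) {
        net[e] <- (if (e %in% names(net)) net[[e]] else 0) +
          r$stoichiometry[[k]] * cnt[[e]]
      }
    }
    charges <- vapply(mets, function(m) {
      ch <- model$metabolites[[m]]$charge
      if (is.na(ch)) 0 else as.numeric(ch)
    }, numeric(1))
    net_charge <- sum(r$stoichiometry * charges)
    bad <- net[abs(net) > 1e-9]
    unbalanced <- length(bad) > 0 || abs(net_charge) > 1e-9
    imb <- paste(c(
      if (length(bad) > 0) paste0(names(bad), ":", bad),
      if (abs(net_charge) > 1e-9) paste0("charge:", net_charge)),
      collapse = " ")
    data.frame(reaction = r$id,
               status = if (unbalanced) "unbalanced" else "balanced",
               imbalance = imb, net_charge = net_charge,
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(pass = !any(report$status == "unbalanced"), report = report)
}

#' Dead-end metabolite detection and three-way classification
#'
#' A structural scan of producer and consumer sets per metabolite,
#' treating reversible reactions (lower bound < 0 < upper bound) as
#' both producers and consumers of everything they touch. Disconnected
#' metabolites are classified by their disconnection motive:
#' `single_reaction` (present in exactly one reaction),
#' `substrate_only` (only ever consumed), `product_only` (only ever
#' produced). Metabolites produced and consumed by two or more
#' reactions are connected and absent from the report. Boundary
#' pseudo-reactions count as producers/consumers like any other, so an
#' extracellular metabolite with an exchange is not a dead end.
#'
#' @param model a [metabolic_model()].
#' @return data.frame with columns `metabolite` and `class`; zero rows
#'   when the network has no dead ends. Sorted by metabolite id.
#' @export
find_dead_ends <- function(model) {
  met_ids <- names(model$metabolites)
  n_rxn <- stats::setNames(integer(length(met_ids)), met_ids)
  produced <- stats::setNames(logical(length(met_ids)), met_ids)
  consumed <- stats::setNames(logical(length(met_ids)), met_ids)
  for (r in model$reactions) {
    st <- r$stoichiometry
    if (length(st) == 0) next
    rev <- r$lower_bound < 0 && r$upper_bound > 0
    mets <- names(st)
    n_rxn[mets] <- n_rxn[mets] + 1L
    produced[mets[st > 0]] <- TRUE
    consumed[mets[st < 0]] <- TRUE
    if (rev) {
      produced[mets] <- TRUE
      consumed[mets] <- TRUE
    }
  }
  cls <- character(0); ids <- character(0)
  for (m in met_ids) {
    if (n_rxn[[m]] == 0) next     # unused metabolite record, not a dead end
    if (n_rxn[[m]] == 1L) {
      ids <- c(ids, m); cls <- c(cls, "single_reaction")
    } else if (!produced[[m]]) {
      ids <- c(ids, m); cls <- c(cls, "substrate_only")
    } else if (!consumed[[m]]) {
      ids <- c(ids, m); cls <- c(cls, "product_only")
    }
  }
  out <- data.frame(metabolite = ids, class = cls,
                    stringsAsFactors = FALSE)
  out[order(out$metabolite), , drop = FALSE]
}

#' Orphan reactions (no gene association), grouped by subsystem
#'
#' @param model a [metabolic_model()].
#' @return list with `orphans` (sorted reaction ids with empty GPR) and
#'   `by_subsystem` (data.frame `subsystem`, `count`). Boundary
#'   pseudo-reactions (exchange/sink/demand/biomass), which never carry
#'   genes, are excluded.
#' @export
list_orphans <- function(model) {
  cand <- Filter(function(r) {
    !(r$kind %in% c("exchange", "sink", "demand", "biomass")) &&
      !nzchar(r$gpr)
  }, model$reactions)
  ids <- sort(unname(vapply(cand, `[[`, character(1), "id")))
  subs <- vapply(cand[ids], function(r) {
    if (is.na(r$subsystem)) "(unassigned)" else r$subsystem
  }, character(1))
  tab <- if (length(subs) > 0) {
    counts <- table(subs)
    data.frame(subsystem = names(counts),
               count = as.integer(counts),
               stringsAsFactors = FALSE)
  } else {
    data.frame(subsystem = character(0), count = integer(0),
               stringsAsFactors = FALSE)
  }
  list(orphans = ids, by_subsystem = tab)
}
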