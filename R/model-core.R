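#' Stoichiometric model container
#'
#' A `metabolic_model` is the in-memory representation of a
#' constraint-based (genome-scale) metabolic network: compartmentalised
#' metabolites, reactions with flux bounds and GPR rules, a gene list
#' and a single objective reaction (by convention the biomass
#' pseudo-reaction). Fluxes are in mmol per gram dry weight per hour;
#' the growth rate (flux through the biomass reaction) is in per hour.
#'
#' @param id reaction or metabolite identifier. Metabolite ids carry a
#'   compartment suffix (`"_c"`, `"_p"`, `"_e"` for cytoplasm, periplasm
#'   and extracellular space in the default three-compartment layout).
#' @param name human-readable name.
#' @param formula chemical formula in Hill notation (e.g. `"C6H12O6"`),
#'   or `NA` when unknown.
#' @param charge integer formal charge, or `NA`.
#' @param compartment compartment id the metabolite belongs to.
#' @return `metabolite()` returns a metabolite record (named list).
#' @export
metabolite <- function(id, name = id, formula = NA_character_,
                       charge = NA_integer_, compartment) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  list(id = id, name = name, formula = formula,
       charge = as.integer(charge), compartment = compartment)
}

#' @rdname metabolite
#' @param stoichiometry named numeric vector, metabolite id to signed
#'   coefficient (negative = consumed, positive = produced).
#' @param lower_bound,upper_bound flux bounds (mmol/gDW/h). Infinite
#'   bounds are clamped to the global convention of +/-1000 when the
#'   model is solved.
#' @param gpr GPR rule string (see [parse_gpr()]); `""` marks an orphan
#'   reaction.
#' @param subsystem pathway subsystem label.
#' @param kind one of `"internal"`, `"transport"`, `"exchange"`,
#'   `"sink"`, `"demand"`, `"biomass"`; `NA` asks [infer_reaction_kind()]
#'   to classify it when added to a model.
#' @return `reaction()` returns a reaction record (named list).
#' @export
reaction <- function(id, stoichiometry, lower_bound = 0,
                     upper_bound = 1000, gpr = "", name = id,
                     subsystem = NA_character_, kind = NA_character_) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stoichiometry <- stoichiometry[stoichiometry != 0]
  if (length(stoichiometry) > 0 && is.null(names(stoichiometry))) {
    stop("stoichiometry must be a named numeric vector", call. = FALSE)
  }
  if (lower_bound > upper_bound) {
    stop("reaction ", id, ": lower_bound > upper_bound", call. = FALSE)
  }
  list(id = id, name = name,
       stoichiometry = stoichiometry,
       lower_bound = as.numeric(lower_bound),
       upper_bound = as.numeric(upper_bound),
       gpr = if (is.null(gpr) || is.na(gpr)) "" else gpr,
       gpr_ast = parse_gpr(gpr),
       subsystem = subsystem,
       kind = kind)
}

REACTION_KINDS <- c("internal", "transport", "exchange", "sink",
                    "demand", "biomass")

#' Assemble a metabolic model
#'
#' @param id model identifier.
#' @param compartments named character vector, compartment id to name.
#' @param metabolites list of [metabolite()] records.
#' @param reactions list of [reaction()] records.
#' @param genes character vector of gene ids; defaults to the union of
#'   genes appearing in GPR rules.
#' @param objective id of the objective reaction (usually biomass).
#' @param extracellular id of the extracellular compartment, used to
#'   classify exchange reactions (default `"e"`).
#' @return an object of class `metabolic_model`.
#' @seealso [read_model()], [fba()], [stoichiometric_matrix()]
#' @export
metabolic_model <- function(id, compartments, metabolites, reactions,
                            genes = NULL, objective = NULL,
                            extracellular = "e") {
  met_ids <- vapply(metabolites, `[[`, character(1), "id")
  rxn_ids <- vapply(reactions, `[[`, character(1), "id")
  names(metabolites) <- met_ids
  names(reactions) <- rxn_ids
  gpr_all <- sort(unique(unlist(lapply(reactions, function(r) {
    gpr_genes(r$gpr_ast)
  }))))
  if (is.null(genes)) genes <- gpr_all
  model <- structure(
    list(id = id,
         compartments = compartments,
         metabolites = metabolites,
         reactions = reactions,
         genes = sort(unique(c(genes, gpr_all))),
         objective = objective,
         extracellular = extracellular),
    class = "metabolic_model")
  # dangling stoichiometry references must be caught before kind
  # inference tries to look compartments up
  for (r in model$reactions) {
    dangling <- setdiff(names(r$stoichiometry), met_ids)
    if (length(dangling) > 0) {
      stop("integrity error: reaction ", r$id,
           " references undeclared metabolites: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
  }
  for (rid in rxn_ids) {
    if (is.na(model$reactions[[rid]]$kind)) {
      model$reactions[[rid]]$kind <- infer_reaction_kind(model, rid)
    }
  }
  validate_model(model)
  model
}

#' Classify a reaction as internal, transport, exchange, sink or biomass
#'
#' Exchange reactions touch exactly one metabolite, in the extracellular
#' compartment; sink/demand reactions touch one intracellular metabolite
#' (consumed); biomass is recognised from the objective or a `BIOMASS`/
#' `bof` id prefix; reactions spanning two or more compartments are
#' transport; everything else is internal.
#'
#' @param model a `metabolic_model`.
#' @param rxn_id reaction id.
#' @return a kind string (see [reaction()]).
#' @export
infer_reaction_kind <- function(model, rxn_id) {
  r <- model$reactions[[rxn_id]]
  mets <- names(r$stoichiometry)
  if (grepl("^(BIOMASS|biomass|bof)", r$id) ||
      identical(model$objective, r$id)) {
    return("biomass")
  }
  if (length(mets) == 1L) {
    comp <- model$metabolites[[mets]]$compartment
    if (identical(comp, model$extracellular)) return("exchange")
    return("sink")
  }
  comps <- unique(vapply(mets, function(m) {
    model$metabolites[[m]]$compartment
  }, character(1)))
  if (length(comps) > 1L) "transport" else "internal"
}

#' Validate model integrity
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a
#' declared metabolite, every metabolite compartment is declared, every
#' GPR leaf is a known gene, bounds are ordered, and exchange reactions
#' touch exactly one extracellular metabolite.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly; stops with an integrity error listing
#'   the offending ids otherwise.
#' @export
validate_model <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  if (anyDuplicated(met_ids)) {
    stop("integrity error: duplicated metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxn_ids)) {
    stop("integrity error: duplicated reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad_comp <- met_ids[!vapply(model$metabolites, function(m) {
    m$compartment %in% names(model$compartments)
  }, logical(1))]
  if (length(bad_comp) > 0) {
    stop("integrity error: metabolites in undeclared compartments: ",
         paste(bad_comp, collapse = ", "), call. = FALSE)
  }
  for (r in model$reactions) {
    dangling <- setdiff(names(r$stoichiometry), met_ids)
    if (length(dangling) > 0) {
      stop("integrity error: reaction ", r$id,
           " references undeclared metabolites: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
    if (r$lower_bound > r$upper_bound) {
      stop("integrity error: reaction ", r$id, " has lower_bound > upper_bound",
           call. = FALSE)
    }
    unknown_genes <- setdiff(gpr_genes(r$gpr_ast), model$genes)
    if (length(unknown_genes) > 0) {
      stop("integrity error: reaction ", r$id,
           " GPR references unknown genes: ",
           paste(unknown_genes, collapse = ", "), call. = FALSE)
    }
    if (identical(r$kind, "exchange")) {
      mets <- names(r$stoichiometry)
      ok <- length(mets) == 1L &&
        identical(model$metabolites[[mets]]$compartment, model$extracellular)
      if (!ok) {
        stop("integrity error: exchange reaction ", r$id,
             " must touch exactly one extracellular metabolite",
             call. = FALSE)
      }
    }
  }
  if (!is.null(model$objective) && !model$objective %in% rxn_ids) {
    stop("integrity error: objective reaction ", model$objective,
         " not in model", call. = FALSE)
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", length(x$metabolites),
      "  reactions: ", length(x$reactions),
      "  genes: ", length(x$genes), "\n", sep = "")
  cat("  compartments: ",
      paste(names(x$compartments), collapse = ", "), "\n", sep = "")
  cat("  objective: ", if (is.null(x$objective)) "<none>" else x$objective,
      "\n", sep = "")
  invisible(x)
}

#' Reaction ids of a given kind
#'
#' @param model a `metabolic_model`.
#' @param kind one of the reaction kinds (see [reaction()]).
#' @return character vector of reaction ids.
#' @export
reactions_of_kind <- function(model, kind) {
  ids <- names(model$reactions)
  ids[vapply(model$reactions, function(r) identical(r$kind, kind),
             logical(1))]
}

#' Stoichiometric matrix
#'
#' Builds the sparse matrix S with one row per metabolite and one column
#' per reaction; entry (i, j) is the signed coefficient of metabolite i
#' in reaction j. Steady state mass balance is S v = 0.
#'
#' @param model a `metabolic_model`.
#' @return a `dgCMatrix` with metabolite ids as rownames and reaction
#'   ids as colnames; 0 x 0 for an empty model.
#' @export
stoichiometric_matrix <- function(model) {
  met_ids <- names(model$metabolites)
  rxn_ids <- names(model$reactions)
  if (length(met_ids) == 0 || length(rxn_ids) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(length(met_ids), length(rxn_ids)),
                                dimnames = list(met_ids, rxn_ids)))
  }
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    st <- model$reactions[[j]]$stoichiometry
    if (length(st) == 0) next
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Merge duplicated metabolites under a synonym map
#'
#' Rewrites every stoichiometry through `synonym_map` (old id ->
#' canonical id), summing coefficient collisions inside a reaction.
#' Reactions whose stoichiometry becomes empty (a substrate and product
#' merged to zero net coefficient) are removed and reported as
#' degenerate rather than silently kept.
#'
#' @param model a `metabolic_model`.
#' @param synonym_map named character vector, old metabolite id ->
#'   canonical metabolite id.
#' @return the rewritten model, with attribute `"degenerate"` listing
#'   the ids of removed zero-net reactions.
#' @export
merge_duplicate_metabolites <- function(model, synonym_map) {
  if (length(synonym_map) == 0) {
    attr(model, "degenerate") <- character(0)
    return(model)
  }
  canon <- function(ids) {
    hit <- ids %in% names(synonym_map)
    ids[hit] <- unname(synonym_map[ids[hit]])
    ids
  }
  degenerate <- character(0)
  keep <- rep(TRUE, length(model$reactions))
  for (j in seq_along(model$reactions)) {
    st <- model$reactions[[j]]$stoichiometry
    if (length(st) == 0) next
    new_ids <- canon(names(st))
    merged <- tapply(unname(st), new_ids, sum)
    merged <- merged[abs(merged) > 1e-9]
    if (length(merged) == 0) {
      degenerate <- c(degenerate, model$reactions[[j]]$id)
      keep[j] <- FALSE
    } else {
      v <- as.numeric(merged)
      names(v) <- names(merged)
      model$reactions[[j]]$stoichiometry <- v
    }
  }
  model$reactions <- model$reactions[keep]
  # drop replaced metabolite records; keep canonical targets
  drop_ids <- setdiff(names(synonym_map), unname(synonym_map))
  model$metabolites <- model$metabolites[
    setdiff(names(model$metabolites), drop_ids)]
  missing_canon <- setdiff(unname(synonym_map), names(model$metabolites))
  if (length(missing_canon) > 0) {
    stop("merge error: canonical ids not present in model: ",
         paste(missing_canon, collapse = ", "), call. = FALSE)
  }
  validate_model(model)
  attr(model, "degenerate") <- degenerate
  model
}

#' Reassign all metabolites of one compartment to another
#'
#' Moves every metabolite in `from` to `to`, rewriting the conventional
#' `_<compartment>` id suffix. Duplicates created by the move (a
#' metabolite already present in `to`) are absorbed via
#' [merge_duplicate_metabolites()]. Used to fold template-model relic
#' compartments (thylakoid, carboxysome) into the three-compartment
#' layout of a non-photosynthetic-membrane organism.
#'
#' @param model a `metabolic_model`.
#' @param from,to declared compartment ids.
#' @return the rewritten model; the `from` compartment is removed from
#'   the declaration when emptied.
#' @export
reassign_compartment <- function(model, from, to) {
  if (!from %in% names(model$compartments) ||
      !to %in% names(model$compartments)) {
    stop("both compartments must be declared", call. = FALSE)
  }
  moving <- names(model$metabolites)[vapply(model$metabolites, function(m) {
    identical(m$compartment, from)
  }, logical(1))]
  if (length(moving) == 0) {
    model$compartments <- model$compartments[
      names(model$compartments) != from]
    return(model)
  }
  suffix_re <- paste0("_", from, "$")
  new_ids <- ifelse(grepl(suffix_re, moving),
                    sub(suffix_re, paste0("_", to), moving),
                    paste0(moving, "_", to))
  synonym <- stats::setNames(new_ids, moving)
  # register moved metabolites under their new id (unless already there)
  for (k in seq_along(moving)) {
    old <- moving[k]; new <- new_ids[k]
    if (!new %in% names(model$metabolites)) {
      m <- model$metabolites[[old]]
      m$id <- new
      m$compartment <- to
      model$metabolites[[new]] <- m
    }
  }
  model <- merge_duplicate_metabolites(model, synonym)
  model$compartments <- model$compartments[names(model$compartments) != from]
  validate_model(model)
  model
}

#' Add or replace a reaction in a model
#'
#' @param model a `metabolic_model`.
#' @param rxn a [reaction()] record; metabolites it references must
#'   already exist in the model.
#' @return the updated model.
#' @export
add_reaction <- function(model, rxn) {
  if (is.na(rxn$kind)) {
    model$reactions[[rxn$id]] <- rxn
    model$reactions[[rxn$id]]$kind <- infer_reaction_kind(model, rxn$id)
  } else {
    model$reactions[[rxn$id]] <- rxn
  }
  model$genes <- sort(unique(c(model$genes, gpr_genes(rxn$gpr_ast))))
  validate_model(model)
  model
}

#' Remove reactions from a model
#'
#' @param model a `metabolic_model`.
#' @param rxn_ids reaction ids to drop.
#' @return the updated model.
#' @export
remove_reactions <- function(model, rxn_ids) {
  model$reactions <- model$reactions[
    setdiff(names(model$reactions), rxn_ids)]
  model
}
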