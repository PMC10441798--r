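#' Read and write stoichiometric models
#'
#' Two interchange formats are supported: the COBRA-style JSON schema
#' (top-level `metabolites`, `reactions`, `genes`, with
#' `objective_coefficient` marking the objective) so published models
#' load unmodified, and SBML Level 3 with the `fbc` package (flux
#' bounds, gene products and objectives). Writers emit ids in sorted
#' order so outputs are diff-stable.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; inferred from the file extension
#'   when `NULL`.
#' @return `read_model()` returns a validated [metabolic_model()].
#' @export
read_model <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "json"
  }
  switch(match.arg(format, c("json", "sbml")),
         json = read_model_json(path),
         sbml = read_model_sbml(path))
}

#' @rdname read_model
#' @param model a `metabolic_model`.
#' @return `write_model()` returns `path`, invisibly.
#' @export
write_model <- function(model, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) {
      "sbml"
    } else "json"
  }
  switch(match.arg(format, c("json", "sbml")),
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop("format error parsing JSON model ", path, ": ",
           conditionMessage(e), call. = FALSE)
    })
  for (fld in c("metabolites", "reactions")) {
    if (is.null(doc[[fld]])) {
      stop("format error: JSON model lacks '", fld, "' field", call. = FALSE)
    }
  }
  compartments <- if (!is.null(doc$compartments)) {
    unlist(doc$compartments)
  } else {
    comps <- unique(vapply(doc$metabolites, function(m) {
      m$compartment %||% sub("^.*_", "", m$id)
    }, character(1)))
    stats::setNames(comps, comps)
  }
  mets <- lapply(doc$metabolites, function(m) {
    metabolite(id = m$id,
               name = m$name %||% m$id,
               formula = m$formula %||% NA_character_,
               charge = m$charge %||% NA_integer_,
               compartment = m$compartment %||% sub("^.*_", "", m$id))
  })
  objective <- NULL
  rxns <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) st <- stats::setNames(numeric(0), character(0))
    if (!is.null(r$objective_coefficient) &&
        r$objective_coefficient != 0) {
      objective <<- r$id
    }
    reaction(id = r$id, name = r$name %||% r$id,
             stoichiometry = st,
             lower_bound = r$lower_bound %||% 0,
             upper_bound = r$upper_bound %||% 1000,
             gpr = r$gene_reaction_rule %||% "",
             subsystem = r$subsystem %||% NA_character_,
             kind = r$kind %||% NA_character_)
  })
  genes <- if (!is.null(doc$genes)) {
    vapply(doc$genes, function(g) g$id %||% as.character(g), character(1))
  } else NULL
  metabolic_model(id = doc$id %||% basename(path),
                  compartments = compartments,
                  metabolites = mets, reactions = rxns,
                  genes = genes, objective = objective,
                  extracellular = doc$extracellular %||% "e")
}

write_model_json <- function(model, path) {
  mets <- lapply(model$metabolites[sort(names(model$metabolites))],
                 function(m) {
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$charge)) out$charge <- m$charge
    out
  })
  rxns <- lapply(model$reactions[sort(names(model$reactions))],
                 function(r) {
    list(id = r$id, name = r$name,
         metabolites = as.list(r$stoichiometry),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         gene_reaction_rule = r$gpr,
         subsystem = r$subsystem,
         kind = r$kind,
         objective_coefficient =
           if (identical(model$objective, r$id)) 1 else 0)
  })
  doc <- list(id = model$id,
              compartments = as.list(model$compartments),
              extracellular = model$extracellular,
              metabolites = unname(mets),
              reactions = unname(rxns),
              genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

SBML_NS <- c(
  sbml = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("format error parsing SBML ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "sbml")
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", ns)
  if (inherits(mdl, "xml_missing")) {
    stop("format error: no <model> element in ", path, call. = FALSE)
  }
  sid <- function(node, attr = "id") xml2::xml_attr(node, attr)

  comp_nodes <- xml2::xml_find_all(
    mdl, ".//sbml:listOfCompartments/sbml:compartment", ns)
  compartments <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(comp_nodes, "name")),
           sid(comp_nodes), xml2::xml_attr(comp_nodes, "name")),
    sid(comp_nodes))

  # numeric flux-bound parameters
  par_nodes <- xml2::xml_find_all(
    mdl, ".//sbml:listOfParameters/sbml:parameter", ns)
  params <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")), sid(par_nodes))

  sp_nodes <- xml2::xml_find_all(
    mdl, ".//sbml:listOfSpecies/sbml:species", ns)
  mets <- lapply(sp_nodes, function(nd) {
    ch <- xml2::xml_attr(nd, "fbc:charge", ns = ns)
    fm <- xml2::xml_attr(nd, "fbc:chemicalFormula", ns = ns)
    metabolite(id = sid(nd),
               name = xml2::xml_attr(nd, "name") %||% sid(nd),
               formula = fm,
               charge = if (is.na(ch)) NA_integer_ else as.integer(ch),
               compartment = xml2::xml_attr(nd, "compartment"))
  })
  met_ids <- vapply(mets, `[[`, character(1), "id")

  gp_nodes <- xml2::xml_find_all(
    mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gene_label <- stats::setNames(
    xml2::xml_attr(gp_nodes, "fbc:label", ns = ns),
    xml2::xml_attr(gp_nodes, "fbc:id", ns = ns))
  gene_label[is.na(gene_label)] <- names(gene_label)[is.na(gene_label)]

  objective <- NULL
  obj_flux <- xml2::xml_find_first(
    mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective",
    ns)
  if (!inherits(obj_flux, "xml_missing")) {
    objective <- xml2::xml_attr(obj_flux, "fbc:reaction", ns = ns)
  }

  rxn_nodes <- xml2::xml_find_all(
    mdl, ".//sbml:listOfReactions/sbml:reaction", ns)
  rxns <- lapply(rxn_nodes, function(nd) {
    rid <- sid(nd)
    get_side <- function(xp, sign) {
      refs <- xml2::xml_find_all(nd, xp, ns)
      if (length(refs) == 0) return(stats::setNames(numeric(0), character(0)))
      sp <- xml2::xml_attr(refs, "species")
      bad <- setdiff(sp, met_ids)
      if (length(bad) > 0) {
        stop("integrity error: reaction ", rid,
             " cites undeclared species: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      coef <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      coef[is.na(coef)] <- 1
      stats::setNames(sign * coef, sp)
    }
    st_sub <- get_side(".//sbml:listOfReactants/sbml:speciesReference", -1)
    st_prod <- get_side(".//sbml:listOfProducts/sbml:speciesReference", 1)
    st <- c(st_sub, st_prod)
    collapsed <- tapply(unname(st), names(st), sum)
    st <- stats::setNames(as.numeric(collapsed), names(collapsed))

    lb_ref <- xml2::xml_attr(nd, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(nd, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(params)) {
      params[[lb_ref]]
    } else if (identical(xml2::xml_attr(nd, "reversible"), "true")) {
      -1000
    } else 0
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(params)) {
      params[[ub_ref]]
    } else 1000

    gpr_node <- xml2::xml_find_first(
      nd, ".//fbc:geneProductAssociation", ns)
    gpr <- if (inherits(gpr_node, "xml_missing")) {
      ""
    } else {
      sbml_gpa_to_string(xml2::xml_child(gpr_node), gene_label, ns)
    }
    reaction(id = rid, name = xml2::xml_attr(nd, "name") %||% rid,
             stoichiometry = st, lower_bound = lb, upper_bound = ub,
             gpr = gpr)
  })
  genes <- sort(unique(unname(gene_label)))
  metabolic_model(id = sid(mdl) %||% basename(path),
                  compartments = compartments,
                  metabolites = mets, reactions = rxns,
                  genes = if (length(genes)) genes else NULL,
                  objective = objective)
}

sbml_gpa_to_string <- function(node, gene_label, ns) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    gid <- xml2::xml_attr(node, "fbc:geneProduct", ns = ns)
    return(if (gid %in% names(gene_label)) gene_label[[gid]] else gid)
  }
  kids <- xml2::xml_children(node)
  parts <- vapply(kids, sbml_gpa_to_string, character(1),
                  gene_label = gene_label, ns = ns)
  op <- if (nm == "and") " and " else " or "
  paste0("(", paste(parts, collapse = op), ")")
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  sanitize <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_NS[["sbml"]], '" xmlns:fbc="',
           SBML_NS[["fbc"]],
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', esc(sanitize(model$id)),
           '" fbc:strict="true">'),
    "    <listOfCompartments>")
  for (cid in sort(names(model$compartments))) {
    lines <- c(lines, paste0(
      '      <compartment id="', cid, '" name="',
      esc(model$compartments[[cid]]), '" constant="true"/>'))
  }
  lines <- c(lines, "    </listOfCompartments>", "    <listOfSpecies>")
  for (mid in sort(names(model$metabolites))) {
    m <- model$metabolites[[mid]]
    extra <- ""
    if (!is.na(m$formula)) {
      extra <- paste0(extra, ' fbc:chemicalFormula="', esc(m$formula), '"')
    }
    if (!is.na(m$charge)) {
      extra <- paste0(extra, ' fbc:charge="', m$charge, '"')
    }
    lines <- c(lines, paste0(
      '      <species id="', mid, '" name="', esc(m$name),
      '" compartment="', m$compartment,
      '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
      ' constant="false"', extra, "/>"))
  }
  lines <- c(lines, "    </listOfSpecies>")

  # flux-bound parameters, deduplicated by value
  rids <- sort(names(model$reactions))
  bounds <- sort(unique(unlist(lapply(model$reactions, function(r) {
    c(r$lower_bound, r$upper_bound)
  }))))
  par_id <- stats::setNames(
    paste0("FB_", seq_along(bounds)), sprintf("%.17g", bounds))
  lines <- c(lines, "    <listOfParameters>")
  for (k in seq_along(bounds)) {
    lines <- c(lines, paste0(
      '      <parameter id="FB_', k, '" value="', bounds[k],
      '" constant="true"/>'))
  }
  lines <- c(lines, "    </listOfParameters>")

  gene_ids <- stats::setNames(
    paste0("G_", sanitize(model$genes)), model$genes)
  if (length(model$genes) > 0) {
    lines <- c(lines, "    <fbc:listOfGeneProducts>")
    for (g in model$genes) {
      lines <- c(lines, paste0(
        '      <fbc:geneProduct fbc:id="', gene_ids[[g]],
        '" fbc:label="', esc(g), '"/>'))
    }
    lines <- c(lines, "    </fbc:listOfGeneProducts>")
  }

  gpa_xml <- function(tree, indent) {
    pad <- strrep(" ", indent)
    if (is.character(tree)) {
      return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="',
                    gene_ids[[tree]], '"/>'))
    }
    tag <- paste0("fbc:", tree$op)
    c(paste0(pad, "<", tag, ">"),
      unlist(lapply(tree$args, gpa_xml, indent = indent + 2)),
      paste0(pad, "</", tag, ">"))
  }

  lines <- c(lines, "    <listOfReactions>")
  for (rid in rids) {
    r <- model$reactions[[rid]]
    lbp <- par_id[[sprintf("%.17g", r$lower_bound)]]
    ubp <- par_id[[sprintf("%.17g", r$upper_bound)]]
    lines <- c(lines, paste0(
      '      <reaction id="', sanitize(rid), '" name="', esc(r$name),
      '" reversible="', tolower(r$lower_bound < 0),
      '" fast="false" fbc:lowerFluxBound="', lbp,
      '" fbc:upperFluxBound="', ubp, '">'))
    subs <- r$stoichiometry[r$stoichiometry < 0]
    prods <- r$stoichiometry[r$stoichiometry > 0]
    if (length(subs) > 0) {
      lines <- c(lines, "        <listOfReactants>")
      for (m in sort(names(subs))) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', m,
          '" stoichiometry="', -subs[[m]], '" constant="true"/>'))
      }
      lines <- c(lines, "        </listOfReactants>")
    }
    if (length(prods) > 0) {
      lines <- c(lines, "        <listOfProducts>")
      for (m in sort(names(prods))) {
        lines <- c(lines, paste0(
          '          <speciesReference species="', m,
          '" stoichiometry="', prods[[m]], '" constant="true"/>'))
      }
      lines <- c(lines, "        </listOfProducts>")
    }
    if (nzchar(r$gpr)) {
      lines <- c(lines,
                 "        <fbc:geneProductAssociation>",
                 gpa_xml(r$gpr_ast, 10),
                 "        </fbc:geneProductAssociation>")
    }
    lines <- c(lines, "      </reaction>")
  }
  lines <- c(lines, "    </listOfReactions>")
  if (!is.null(model$objective)) {
    lines <- c(lines,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      "        <fbc:listOfFluxObjectives>",
      paste0('          <fbc:fluxObjective fbc:reaction="',
             sanitize(model$objective), '" fbc:coefficient="1"/>'),
      "        </fbc:listOfFluxObjectives>",
      "      </fbc:objective>",
      "    </fbc:listOfObjectives>")
  }
  lines <- c(lines, "  </model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
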